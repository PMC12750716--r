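# Nonparametric bootstrap of the full G-computation pipeline with
# normal and Efron bias-corrected percentile intervals, z statistics
# and p values. Resampling unit = participant record; per-replicate
# seeds are derived from the master seed by counter so a dropped
# replicate never shifts the stream of any other.

#' Efron bias-corrected percentile interval
#'
#' `z0 = qnorm((#\{theta* < theta_hat\} + 0.5 * #\{theta* = theta_hat\}) / B)`;
#' the bounds are the empirical quantiles (nearest-rank rule,
#' `ceiling(B * p)`) at `pnorm(2 * z0 -+ z_alpha)`. When the count
#' fraction is 0 or 1 it is clamped to `0.5/B` / `1 - 0.5/B` (flagged
#' via attribute `clamped`); identical replicates give the degenerate
#' interval `(point, point)`.
#'
#' @param replicates numeric vector of bootstrap replicates (finite).
#' @param point full-sample point estimate.
#' @param level confidence level, default 0.95.
#' @return Numeric `c(lo, hi)`, attributes `z0` and `clamped`.
#' @export
bc_interval <- function(replicates, point, level = 0.95) {
  b <- length(replicates)
  gc_assert(b >= 2L, "need at least 2 bootstrap replicates")
  gc_assert(all(is.finite(replicates)) && is.finite(point),
            "replicates and point must be finite")
  if (all(replicates == point)) {
    return(structure(c(point, point), z0 = 0, clamped = FALSE))
  }
  frac <- (sum(replicates < point) + 0.5 * sum(replicates == point)) / b
  clamped <- frac <= 0 || frac >= 1
  frac <- min(max(frac, 0.5 / b), 1 - 0.5 / b)
  z0 <- stats::qnorm(frac)
  za <- stats::qnorm((1 + level) / 2)
  p_lo <- stats::pnorm(2 * z0 - za)
  p_hi <- stats::pnorm(2 * z0 + za)
  s <- sort(replicates)
  rank_at <- function(p) min(max(ceiling(b * p), 1L), b)
  structure(c(s[rank_at(p_lo)], s[rank_at(p_hi)]), z0 = z0,
            clamped = clamped)
}

#' Wald z statistic and p value from a bootstrap SE
#'
#' @param point point estimate.
#' @param se bootstrap standard error (>= 0).
#' @return List `z`, `p`; both `NA` (flagged via `defined = FALSE`)
#'   when `se` is zero.
#' @export
wald_summary <- function(point, se) {
  gc_assert(se >= 0, "standard error must be non-negative")
  if (se == 0) return(list(z = NA_real_, p = NA_real_, defined = FALSE))
  z <- point / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), defined = TRUE)
}

#' Bootstrap the G-computation mediation pipeline
#'
#' Draws `B` resamples of the records with replacement; for each, the
#' entire pipeline (refit the M and Y equations, re-simulate the
#' counterfactual means with a fresh derived seed) is rerun.
#' Non-convergent replicates are dropped and counted; if more than 5%
#' fail the run aborts, since silently dropping many replicates biases
#' the intervals.
#'
#' @param data derived analysis table.
#' @param dag,adjustment,mediator_scale,m_binary_family,exposure,outcome,mc_draws,interaction,draw_y
#'   passed to [gcomp_estimate()].
#' @param B number of bootstrap resamples, default 1000.
#' @param rng_seed master integer seed.
#' @param level confidence level, default 0.95.
#' @return An `inference_table`: per estimand (tce, nde, nie) the point
#'   estimate, bootstrap SE, z, p, normal CI and bias-corrected CI,
#'   plus the proportion-mediated point estimate, replicate matrix and
#'   failure counts.
#' @export
gcomp_bootstrap <- function(data, dag = NULL, adjustment = NULL,
                            mediator_scale = c("binary", "raw"),
                            m_binary_family = c("linear_probability",
                                                "binomial"),
                            exposure = "x_helpful",
                            outcome = "y_exclusive",
                            B = 1000L, mc_draws = 100L, rng_seed = 1L,
                            level = 0.95, interaction = FALSE,
                            draw_y = FALSE) {
  gc_assert(B >= 2L, "B must be >= 2")
  point <- gcomp_estimate(data, dag = dag, adjustment = adjustment,
                          mediator_scale = mediator_scale,
                          m_binary_family = m_binary_family,
                          exposure = exposure, outcome = outcome,
                          mc_draws = mc_draws, rng_seed = rng_seed,
                          interaction = interaction, draw_y = draw_y)
  cfg <- point$config
  mediator <- cfg$mediator
  kind <- if (cfg$mediator_scale == "raw") "gaussian"
    else if (cfg$m_binary_family == "binomial") "binomial"
    else "linear_probability"

  dat <- data
  if (interaction) {
    dat[[paste0(exposure, ":", mediator)]] <-
      dat[[exposure]] * dat[[mediator]]
  }
  Xm <- build_design_matrix(point$model_m$design, dat)
  Xy <- build_design_matrix(point$model_y$design, dat)
  mvec <- as.numeric(dat[[mediator]])
  yvec <- as.numeric(dat[[cfg$outcome]])
  ix_m <- match(exposure, colnames(Xm))
  ix_y <- match(exposure, colnames(Xy))
  im_y <- match(mediator, colnames(Xy))
  iint_y <- match(paste0(exposure, ":", mediator), colnames(Xy))
  if (is.na(iint_y)) iint_y <- 0L
  n <- nrow(Xm)

  reps <- matrix(NA_real_, nrow = B, ncol = 3L,
                 dimnames = list(NULL, c("tce", "nde", "nie")))
  failed <- 0L
  for (b in seq_len(B)) {
    seed_b <- derive_seed(rng_seed, "bootstrap", b)
    set.seed(seed_b)
    idx <- sample.int(n, n, replace = TRUE)
    fm <- gc_fit_m(Xm[idx, , drop = FALSE], mvec[idx], kind)
    fy <- gc_fit_y(Xy[idx, , drop = FALSE], yvec[idx])
    if (!fm$converged || !fy$converged ||
        anyNA(fm$coef) || anyNA(fy$coef)) {
      failed <- failed + 1L
      next
    }
    res <- gc_means_core(fm$coef, fm$sigma, fy$coef,
                         Xm[idx, , drop = FALSE], Xy[idx, , drop = FALSE],
                         ix_m, ix_y, im_y, iint_y, draws = cfg$mc_draws,
                         seed = seed_b, kind = kind, draw_y = cfg$draw_y)
    mu <- res$means
    reps[b, ] <- c(mu["mu_11"] - mu["mu_00"],
                   mu["mu_10"] - mu["mu_00"],
                   mu["mu_11"] - mu["mu_10"])
  }
  if (failed / B > 0.05) {
    gc_stop(sprintf(
      "bootstrap aborted: %d of %d replicates failed to converge", failed, B),
      "gcompmed_bootstrap_error")
  }
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]

  pts <- c(tce = point$estimates$tce, nde = point$estimates$nde,
           nie = point$estimates$nie)
  za <- stats::qnorm((1 + level) / 2)
  results <- lapply(c("tce", "nde", "nie"), function(nm) {
    r <- reps[, nm]
    se <- stats::sd(r)
    w <- wald_summary(pts[[nm]], se)
    list(estimand = nm, point = pts[[nm]], se = se, z = w$z, p = w$p,
         ci_normal = c(pts[[nm]] - za * se, pts[[nm]] + za * se),
         ci_bc = as.numeric(bc_interval(r, pts[[nm]], level)))
  })
  names(results) <- c("tce", "nde", "nie")
  structure(
    list(results = results,
         prop_mediated = point$estimates$prop_mediated,
         prop_defined = point$estimates$prop_defined,
         replicates = reps, b_requested = B, b_failed = failed,
         level = level, point_fit = point, rng_seed = rng_seed),
    class = "inference_table")
}

#' Format an inference table as text
#'
#' Mirrors the study-style results layout: per estimand the G-estimate,
#' bootstrap SE, z statistic, p value, normal CI and bias-corrected CI,
#' rounded to 2 decimals.
#'
#' @param x an `inference_table`.
#' @param digits decimals shown, default 2.
#' @return Character vector of lines.
#' @export
format_inference_table <- function(x, digits = 2) {
  fmt <- function(v) sprintf(paste0("%.", digits, "f"), round_half_up(v, digits))
  ci <- function(v) sprintf("%s to %s", fmt(v[1]), fmt(v[2]))
  header <- sprintf("%-5s %-11s %-12s %-11s %-8s %-15s %-15s",
                    "", "G-estimate", "Bootstrap SE", "z-statistic",
                    "p-value", "95% CI", "95% CI (BC)")
  rows <- vapply(x$results, function(r) {
    sprintf("%-5s %-11s %-12s %-11s %-8s %-15s %-15s",
            toupper(r$estimand), fmt(r$point), fmt(r$se), fmt(r$z),
            fmt(r$p), ci(r$ci_normal), ci(r$ci_bc))
  }, character(1L))
  prop <- if (isTRUE(x$prop_defined)) {
    sprintf("Proportion mediated: %.0f%%", 100 * x$prop_mediated)
  } else {
    "Proportion mediated: undefined (null total effect)"
  }
  c(header, unname(rows), "", prop,
    sprintf("Bootstrap replicates: %d requested, %d failed",
            x$b_requested, x$b_failed))
}

#' @export
print.inference_table <- function(x, ...) {
  writeLines(format_inference_table(x))
  invisible(x)
}

# JSON-ready representation (full precision; replicates omitted).
inference_as_list <- function(x) {
  list(
    estimands = lapply(x$results, function(r) {
      list(point = r$point, se = r$se, z = r$z, p = r$p,
           ci_normal = list(lo = r$ci_normal[1], hi = r$ci_normal[2]),
           ci_bc = list(lo = r$ci_bc[1], hi = r$ci_bc[2]))
    }),
    prop_mediated = if (isTRUE(x$prop_defined)) x$prop_mediated else NULL,
    prop_defined = x$prop_defined,
    b_requested = x$b_requested, b_failed = x$b_failed,
    level = x$level, rng_seed = x$rng_seed,
    counterfactual_means = as.list(x$point_fit$means),
    adjustment = x$point_fit$adjustment,
    mc_draws = x$point_fit$config$mc_draws,
    mediator_scale = x$point_fit$config$mediator_scale,
    model_m = model_as_list(x$point_fit$model_m),
    model_y = model_as_list(x$point_fit$model_y))
}
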