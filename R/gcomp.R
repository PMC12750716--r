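# Monte Carlo G-computation of counterfactual outcome means and the
# natural effect decomposition (TCE / NDE / NIE) on the risk-difference
# scale.
#
# The counterfactual mean E[Y(x, M(x'))] is computed by (i) simulating,
# for every record, `draws` values of the mediator from the fitted
# M-equation with the exposure overridden to x', then (ii) averaging the
# fitted Y-equation probability at exposure x and each simulated
# mediator over records and draws. By default the Y expectation is taken
# analytically given (x, m, C) -- averaging predicted probabilities has
# the same expectation as drawing Bernoulli outcomes but much lower
# Monte Carlo variance; a draw-Y mode exists for fidelity checks.

#' Simulate mediator values under an exposure override
#'
#' @param model_m fitted mediator model (`fitted_model`).
#' @param records data frame of records supplying the confounders.
#' @param x_set exposure level (0 or 1) imposed on every record.
#' @param draws number of simulated mediator values per record.
#' @param rng_seed integer seed.
#' @param exposure exposure column name, default `"x_helpful"`.
#' @param kind mediator simulation family: `"gaussian"` (linear
#'   predictor + normal residual noise), `"linear_probability"`
#'   (Bernoulli with probability the linear predictor clipped to
#'   `[1e-6, 1 - 1e-6]`; clips are counted) or `"binomial"`
#'   (Bernoulli(expit(linear predictor))).
#' @return An `nrow(records) x draws` numeric matrix; for the
#'   linear-probability family, attribute `n_clipped` counts clipped
#'   predictors.
#' @export
simulate_mediator <- function(model_m, records, x_set, draws = 100L,
                              rng_seed = 1L, exposure = "x_helpful",
                              kind = c("gaussian", "linear_probability",
                                       "binomial")) {
  kind <- match.arg(kind)
  gc_assert(model_m$converged, "mediator model did not converge")
  gc_assert(draws >= 1L, "draws must be >= 1")
  recs <- records
  recs[[exposure]] <- x_set
  lp <- predict_linear(model_m, recs)
  n <- length(lp)
  set.seed(derive_seed(rng_seed, "simulate_mediator", x_set))
  if (kind == "gaussian") {
    out <- matrix(stats::rnorm(n * draws, mean = lp,
                               sd = model_m$residual_sd), n, draws)
  } else {
    p <- if (kind == "binomial") expit(lp) else lp
    n_clipped <- if (kind == "linear_probability")
      sum(p < 1e-6 | p > 1 - 1e-6) else 0L
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    out <- matrix(stats::rbinom(n * draws, 1L, p), n, draws)
    attr(out, "n_clipped") <- n_clipped
  }
  out
}

# --- internal fast engine ---------------------------------------------
# Operates on prebuilt design matrices so the bootstrap can refit and
# re-simulate thousands of times without touching data frames.

gc_fit_m <- function(Xm, m, kind) {
  if (kind == "binomial") {
    fit <- suppressWarnings(stats::glm.fit(Xm, m, family = stats::binomial()))
    list(coef = fit$coefficients, sigma = NA_real_,
         converged = isTRUE(fit$converged))
  } else {
    fit <- stats::lm.fit(Xm, m)
    p <- ncol(Xm)
    sigma <- sqrt(sum(fit$residuals^2) / (nrow(Xm) - p))
    list(coef = fit$coefficients, sigma = sigma, converged = TRUE)
  }
}

gc_fit_y <- function(Xy, y) {
  fit <- suppressWarnings(stats::glm.fit(Xy, y, family = stats::binomial()))
  mu <- fit$fitted.values
  separated <- any(mu < 1e-8 | mu > 1 - 1e-8) &&
    max(abs(fit$coefficients)) > 15
  list(coef = fit$coefficients,
       converged = isTRUE(fit$converged) && !separated)
}

# Counterfactual means from fitted coefficient vectors.
# ix_m: exposure column index in Xm; ix_y, im_y, iint_y: exposure,
# mediator, optional exposure-by-mediator interaction columns in Xy
# (iint_y = 0 when absent).
gc_means_core <- function(cm, sigma, cy, Xm, Xy, ix_m, ix_y, im_y,
                          iint_y = 0L, draws, seed, kind, draw_y = FALSE) {
  n <- nrow(Xm)
  lpm_base <- drop(Xm %*% cm) - Xm[, ix_m] * cm[ix_m]
  ly_base <- drop(Xy %*% cy) - Xy[, ix_y] * cy[ix_y] - Xy[, im_y] * cy[im_y]
  if (iint_y > 0L) ly_base <- ly_base - Xy[, iint_y] * cy[iint_y]

  n_clipped <- 0L
  draw_m <- function(x_m) {
    lpm <- lpm_base + x_m * cm[ix_m]
    if (kind == "gaussian") {
      matrix(stats::rnorm(n * draws, mean = lpm, sd = sigma), n, draws)
    } else {
      p <- if (kind == "binomial") expit(lpm) else lpm
      if (kind == "linear_probability") {
        n_clipped <<- n_clipped + sum(p < 1e-6 | p > 1 - 1e-6)
      }
      p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
      matrix(stats::rbinom(n * draws, 1L, p), n, draws)
    }
  }
  one_mean <- function(x_y, x_m) {
    M <- draw_m(x_m)
    slope <- cy[im_y] + if (iint_y > 0L) x_y * cy[iint_y] else 0
    pr <- expit(ly_base + x_y * cy[ix_y] + slope * M)
    if (draw_y) mean(stats::rbinom(length(pr), 1L, pr)) else mean(pr)
  }
  set.seed(derive_seed(seed, "counterfactual_means"))
  mu_11 <- one_mean(1, 1)
  mu_00 <- one_mean(0, 0)
  mu_10 <- one_mean(1, 0)
  list(means = c(mu_11 = mu_11, mu_00 = mu_00, mu_10 = mu_10),
       n_clipped = n_clipped)
}

#' Counterfactual outcome means by Monte Carlo G-computation
#'
#' Computes `mu_11 = E[Y(1, M(1))]`, `mu_00 = E[Y(0, M(0))]` and
#' `mu_10 = E[Y(1, M(0))]`, standardised over the confounder
#' distribution of `records`.
#'
#' @param model_y fitted logistic outcome model (`fitted_model`).
#' @param model_m fitted mediator model.
#' @param records data frame of analysis records.
#' @param draws mediator draws per record, default 100.
#' @param rng_seed integer seed.
#' @param exposure,mediator exposure and mediator column names.
#' @param mediator_kind see [simulate_mediator()].
#' @param draw_y if TRUE, draw Bernoulli outcomes instead of averaging
#'   predicted probabilities.
#' @return Named numeric vector `(mu_11, mu_00, mu_10)` with attribute
#'   `n_clipped`.
#' @export
counterfactual_means <- function(model_y, model_m, records, draws = 100L,
                                 rng_seed = 1L, exposure = "x_helpful",
                                 mediator = "bses_total",
                                 mediator_kind = "gaussian",
                                 draw_y = FALSE) {
  gc_assert(model_y$converged, "outcome model did not converge")
  gc_assert(model_m$converged, "mediator model did not converge")
  Xm <- build_design_matrix(model_m$design, records)
  Xy <- build_design_matrix(model_y$design, records)
  ix_m <- match(exposure, colnames(Xm))
  ix_y <- match(exposure, colnames(Xy))
  im_y <- match(mediator, colnames(Xy))
  gc_assert(!anyNA(c(ix_m, ix_y, im_y)),
            "exposure/mediator columns not found in the fitted designs")
  int_name <- paste0(exposure, ":", mediator)
  iint_y <- match(int_name, colnames(Xy))
  if (is.na(iint_y)) iint_y <- 0L
  res <- gc_means_core(model_m$coefficients, model_m$residual_sd,
                       model_y$coefficients, Xm, Xy, ix_m, ix_y, im_y,
                       iint_y, draws = draws, seed = rng_seed,
                       kind = mediator_kind, draw_y = draw_y)
  out <- res$means
  attr(out, "n_clipped") <- res$n_clipped
  out
}

#' Natural effect decomposition on the risk-difference scale
#'
#' `TCE = mu_11 - mu_00` (the average treatment effect),
#' `NDE = mu_10 - mu_00` (mediator held at its natural unexposed level),
#' `NIE = TCE - NDE` (exactly, by construction), and
#' `prop_mediated = NIE / TCE` when the total effect is non-null.
#'
#' @param means named vector with `mu_11`, `mu_00`, `mu_10` (as from
#'   [counterfactual_means()]).
#' @return A list `tce`, `nde`, `nie`, `prop_mediated`, `prop_defined`;
#'   when `|TCE| < 1e-10` the proportion is `NA` with
#'   `prop_defined = FALSE` rather than a propagated NaN.
#' @export
decompose_effects <- function(means) {
  mu <- means
  gc_assert(all(c("mu_11", "mu_00", "mu_10") %in% names(mu)),
            "means must contain mu_11, mu_00, mu_10")
  gc_assert(all(mu >= 0 & mu <= 1), "counterfactual means must lie in [0,1]")
  tce <- unname(mu["mu_11"] - mu["mu_00"])
  nde <- unname(mu["mu_10"] - mu["mu_00"])
  nie <- tce - nde
  defined <- abs(tce) >= 1e-10
  list(tce = tce, nde = nde, nie = nie,
       prop_mediated = if (defined) nie / tce else NA_real_,
       prop_defined = defined)
}

#' Full G-computation mediation estimate
#'
#' Fits the mediator and outcome equations on adjustment sets taken
#' from a causal DAG (via [mediation_adjustment_sets()]) or supplied
#' explicitly, simulates the counterfactual means and decomposes them.
#' Deterministic given `rng_seed`.
#'
#' @param data derived analysis table.
#' @param dag optional [causal_dag()] whose node names match data
#'   columns (mediator node is remapped to the active mediator column).
#' @param adjustment optional list with elements `mediator` and
#'   `outcome` (character vectors of confounder columns); overrides the
#'   DAG-derived sets.
#' @param mediator_scale `"raw"` (BSES total, linear M-equation) or
#'   `"binary"` (high/low split; see `m_binary_family`).
#' @param m_binary_family for binary mediators, `"linear_probability"`
#'   (linear M-equation, the default) or `"binomial"` (logistic).
#' @param exposure,outcome column names of the exposure and outcome.
#' @param mc_draws mediator draws per record, default 100.
#' @param rng_seed integer seed.
#' @param interaction include an exposure-by-mediator product term in
#'   the Y-equation (default FALSE).
#' @param draw_y draw Bernoulli outcomes instead of averaging
#'   probabilities.
#' @return A `mediation_estimates` object: `estimates` (tce, nde, nie,
#'   prop_mediated), `means`, the fitted `model_m`/`model_y`,
#'   `adjustment`, `n_obs`, `n_clipped` and the configuration echo.
#' @export
gcomp_estimate <- function(data, dag = NULL, adjustment = NULL,
                           mediator_scale = c("binary", "raw"),
                           m_binary_family = c("linear_probability",
                                               "binomial"),
                           exposure = "x_helpful", outcome = "y_exclusive",
                           mc_draws = 100L, rng_seed = 1L,
                           interaction = FALSE, draw_y = FALSE) {
  mediator_scale <- match.arg(mediator_scale)
  m_binary_family <- match.arg(m_binary_family)
  mediator <- if (mediator_scale == "raw") "bses_total" else "m_bses_high"
  gc_assert(all(c(exposure, mediator, outcome) %in% names(data)),
            "data must contain exposure, mediator and outcome columns")

  if (is.null(adjustment)) {
    if (is.null(dag)) {
      gc_stop("supply a DAG or explicit adjustment sets",
              "gcompmed_validation_error")
    }
    sets <- mediation_adjustment_sets(dag)
    if (is.null(sets$chosen$mediator) || is.null(sets$chosen$outcome)) {
      gc_stop("no sufficient adjustment set exists for this DAG",
              "gcompmed_dag_error")
    }
    remap <- function(z) {
      z[z == dag$mediator] <- mediator
      z
    }
    adjustment <- list(mediator = remap(sets$chosen$mediator),
                       outcome = remap(sets$chosen$outcome))
  }
  gc_assert(all(unlist(adjustment) %in% names(data)),
            "adjustment-set variables missing from data")

  mediator_kind <- if (mediator_scale == "raw") "gaussian"
    else if (m_binary_family == "binomial") "binomial"
    else "linear_probability"
  m_family <- if (mediator_kind == "binomial") "binomial_logit"
    else "gaussian_identity"

  dat <- data
  y_terms <- unique(c(exposure, mediator, adjustment$outcome))
  if (interaction) {
    int_col <- paste0(exposure, ":", mediator)
    dat[[int_col]] <- dat[[exposure]] * dat[[mediator]]
    y_terms <- c(y_terms, int_col)
  }
  model_m <- med_fit(design_spec(mediator,
                                 unique(c(exposure, adjustment$mediator)),
                                 family = m_family), dat)
  model_y <- med_fit(design_spec(outcome, y_terms,
                                 family = "binomial_logit"), dat)
  if (!model_m$converged || !model_y$converged) {
    gc_stop(paste0("model non-convergence (mediator: ", model_m$converged,
                   ", outcome: ", model_y$converged, ")"),
            "gcompmed_fit_error")
  }
  means <- counterfactual_means(model_y, model_m, dat, draws = mc_draws,
                                rng_seed = rng_seed, exposure = exposure,
                                mediator = mediator,
                                mediator_kind = mediator_kind,
                                draw_y = draw_y)
  est <- decompose_effects(means)
  structure(
    list(estimates = est, means = means[c("mu_11", "mu_00", "mu_10")],
         model_m = model_m, model_y = model_y, adjustment = adjustment,
         n_obs = nrow(dat), n_clipped = attr(means, "n_clipped"),
         config = list(mediator_scale = mediator_scale,
                       m_binary_family = m_binary_family,
                       mediator = mediator, exposure = exposure,
                       outcome = outcome, mc_draws = mc_draws,
                       rng_seed = rng_seed, interaction = interaction,
                       draw_y = draw_y)),
    class = "mediation_estimates")
}

#' @export
print.mediation_estimates <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("G-computation mediation estimates (n = %d, %d mediator draws)\n",
              x$n_obs, x$config$mc_draws))
  cat(sprintf("  TCE: %+.4f   NDE: %+.4f   NIE: %+.4f\n",
              e$tce, e$nde, e$nie))
  if (e$prop_defined) {
    cat(sprintf("  proportion mediated: %.1f%%\n", 100 * e$prop_mediated))
  } else {
    cat("  proportion mediated: undefined (null total effect)\n")
  }
  invisible(x)
}
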