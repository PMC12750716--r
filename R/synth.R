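# Synthetic cohort generator with known ground truth.
#
# Emulates the statistical structure the analysis assumes: a postpartum
# cohort with a binary exposure (perceiving nurses as always helpful,
# ~43% prevalence), a ceiling-heavy self-efficacy mediator (BSES-SF
# score on [14, 70], generated as a latent gaussian clipped at the
# instrument bounds so that about 55% sit at the ceiling and ~14% fall
# below 56), a binary outcome (exclusive breastfeeding, ~78%
# prevalence) and confounders with study-like marginals (age 29 (6),
# caesarean 29%, HIV 20%, assets 8/13, HLQ-high 76%/70%). Confounders
# are independent apart from a positive age-parity link. True effect
# sizes default to a total causal effect near 0.14 on the risk
# difference scale with a small mediated share, so estimates can be
# validated against an oracle computed from the true models.

#' Data-generating-process configuration
#'
#' @param n number of records.
#' @param x_model named coefficients (logit scale) of the exposure
#'   model: intercept plus confounder terms.
#' @param m_model mediator model: `intercept`, `x` (exposure
#'   coefficient on the latent scale), `coefs` (named confounder
#'   coefficients), `residual_sd`, `clip` (score bounds).
#' @param y_model outcome model (logit scale): `intercept`, `x`, `m`
#'   (coefficient on the mediator as entered), `mediator` (`"binary"`:
#'   the outcome responds to the high/low self-efficacy indicator,
#'   the default; `"raw"`: to the score itself), `m_center` (mediator
#'   centring constant) and `coefs`.
#' @param mediator_scale `"raw"` or `"binary"` analysis intent echoed to
#'   consumers; generation always produces both columns.
#' @param repeat_visit also generate second-visit columns
#'   (`bses_total_v2`, `y_exclusive_v2`, `infant_age_v2`,
#'   `visit2_days_after`).
#' @param rng_seed integer seed.
#' @return A `dgp_config` list.
#' @export
dgp_config <- function(n = 169L,
                       x_model = c(intercept = -0.755, hps_high = 0.5,
                                   education = 0.3, hiv = -0.25,
                                   employment = 0.25, infant_age = -0.02),
                       m_model = list(intercept = 68.1, x = 4.0,
                                      coefs = c(parity = 1.2,
                                                delivery_mode = -2.5,
                                                hps_high = 2.5),
                                      residual_sd = 14.4,
                                      clip = c(14, 70)),
                       y_model = list(intercept = -0.14, x = 0.87,
                                      m = 1.20, mediator = "binary",
                                      m_center = 0,
                                      coefs = c(education = 0.3,
                                                hiv = -0.3,
                                                employment = 0.25,
                                                infant_age = -0.04),
                                      infant_age_center = 4.5),
                       mediator_scale = "binary",
                       repeat_visit = FALSE,
                       rng_seed = 1L) {
  gc_assert(n >= 1L, "n must be >= 1")
  gc_assert(m_model$residual_sd >= 0, "residual_sd must be >= 0")
  structure(list(n = as.integer(n), x_model = x_model, m_model = m_model,
                 y_model = y_model, mediator_scale = mediator_scale,
                 repeat_visit = isTRUE(repeat_visit),
                 rng_seed = as.integer(rng_seed)),
            class = "dgp_config")
}

# Draw the confounder block. Independent marginals calibrated to the
# study's descriptive table, except parity which rises with age.
dgp_confounders <- function(n) {
  maternal_age <- round(pmin(pmax(stats::rnorm(n, 29, 6), 18), 43))
  z_age <- (maternal_age - 29) / 6
  lambda <- 1.08 * exp(0.35 * z_age - 0.35^2 / 2)
  parity <- pmin(stats::rpois(n, lambda), 6L)
  infant_age <- pmax(round(stats::rlnorm(n, log(4.5), 0.75)), 1)
  data.frame(
    maternal_age = maternal_age,
    infant_age = infant_age,
    parity = parity,
    delivery_mode = stats::rbinom(n, 1L, 0.29), # 1 = caesarean
    education = stats::rbinom(n, 1L, 0.64),     # 1 = completed grade 12
    employment = stats::rbinom(n, 1L, 0.25),
    assets = stats::rbinom(n, 13L, 8 / 13),
    hiv = stats::rbinom(n, 1L, 0.20),
    hps_high = stats::rbinom(n, 1L, 0.76),
    hsi_high = stats::rbinom(n, 1L, 0.70),
    relationship = sample(c("married", "relationship_living_alone",
                            "living_with_partner", "single"),
                          n, replace = TRUE,
                          prob = c(0.09, 0.30, 0.25, 0.36)))
}

dgp_lp <- function(coefs, data) {
  lp <- rep(if ("intercept" %in% names(coefs)) coefs[["intercept"]] else 0,
            nrow(data))
  for (nm in setdiff(names(coefs), "intercept")) {
    lp <- lp + coefs[[nm]] * as.numeric(data[[nm]])
  }
  lp
}

# `m` must already be on the scale y_model$mediator names (the raw
# score or the 0/1 high-self-efficacy indicator).
dgp_y_lp <- function(y_model, x, m, data) {
  lp <- y_model$intercept + y_model$x * x +
    y_model$m * (m - y_model$m_center)
  for (nm in names(y_model$coefs)) {
    v <- as.numeric(data[[nm]])
    if (nm == "infant_age") v <- v - y_model$infant_age_center
    lp <- lp + y_model$coefs[[nm]] * v
  }
  lp
}

dgp_m_latent_lp <- function(m_model, x, data) {
  lp <- m_model$intercept + m_model$x * x
  for (nm in names(m_model$coefs)) {
    lp <- lp + m_model$coefs[[nm]] * as.numeric(data[[nm]])
  }
  lp
}

#' Generate a synthetic participant table
#'
#' @param config a [dgp_config()].
#' @param raw if TRUE, additionally emit raw questionnaire columns
#'   (ordinal helpfulness item, 14 BSES items, feeding flags, HLQ items,
#'   asset items) consistent with the derived values, so the derivation
#'   pipeline can be exercised end to end.
#' @return Data frame with one row per mother-infant dyad; attribute
#'   `truth_config` echoes the config.
#' @export
dgp_generate <- function(config, raw = FALSE) {
  set.seed(derive_seed(config$rng_seed, "dgp_generate"))
  n <- config$n
  dat <- dgp_confounders(n)

  x <- stats::rbinom(n, 1L, expit(dgp_lp(config$x_model, dat)))
  lat <- dgp_m_latent_lp(config$m_model, x, dat) +
    stats::rnorm(n, 0, config$m_model$residual_sd)
  clip <- config$m_model$clip
  bses <- as.integer(pmin(pmax(round(lat), clip[1]), clip[2]))
  m_high <- as.integer(bses >= 56L)
  m_for_y <- if (identical(config$y_model$mediator, "raw")) bses else m_high
  y <- stats::rbinom(n, 1L, expit(dgp_y_lp(config$y_model, x, m_for_y, dat)))

  dat$x_helpful <- x
  dat$bses_total <- bses
  dat$m_bses_high <- m_high
  dat$y_exclusive <- y

  if (config$repeat_visit) {
    gap <- ifelse(stats::runif(n) < 0.25, 0L,
                  pmax(round(stats::rlnorm(n, log(7), 0.8)), 1L))
    lat2 <- 0.8 * lat + 0.2 * config$m_model$intercept +
      stats::rnorm(n, 0, 6)
    dat$visit2_days_after <- gap
    dat$infant_age_v2 <- dat$infant_age + gap
    dat$bses_total_v2 <- as.integer(pmin(pmax(round(lat2), clip[1]), clip[2]))
    dat$y_exclusive_v2 <- as.integer(y * stats::rbinom(n, 1L, 0.85))
  }
  if (raw) dat <- dgp_add_raw_columns(dat)
  attr(dat, "truth_config") <- config
  dat
}

# Raw questionnaire columns consistent with the derived ones.
dgp_add_raw_columns <- function(dat) {
  n <- nrow(dat)
  dat$nurse_helpful <- ifelse(
    dat$x_helpful == 1L, "always",
    sample(c("sometimes", "seldom", "never"), n, replace = TRUE,
           prob = c(0.87, 0.12, 0.01)))
  # spread each BSES total over 14 items in [1,5]
  items <- t(vapply(dat$bses_total, function(total) {
    base <- (total - 14L) %/% 14L
    extra <- (total - 14L) %% 14L
    1L + base + c(rep(1L, extra), rep(0L, 14L - extra))
  }, integer(14L)))
  colnames(items) <- paste0("bses_", 1:14)
  dat <- cbind(dat, items)
  cb <- ifelse(dat$y_exclusive == 1L, TRUE,
               stats::runif(n) < 0.49)
  dat$currently_breastfeeding <- cb
  dat$ever_given_other <- ifelse(dat$y_exclusive == 1L, FALSE,
                                 ifelse(cb, TRUE, stats::runif(n) < 0.8))
  for (scale in c("hps", "hsi")) {
    high <- dat[[paste0(scale, "_high")]]
    vals <- ifelse(high == 1L, 3L, 2L)
    for (i in 1:4) dat[[paste0("hlq_", scale, "_", i)]] <- vals
  }
  for (i in 1:13) dat[[paste0("asset_", i)]] <- as.integer(i <= dat$assets)
  dat
}

#' Oracle true effects of a DGP by direct simulation
#'
#' Computes the counterfactual means from the TRUE models (never the
#' fitted ones) on a large simulated confounder sample, averaging exact
#' outcome probabilities, and decomposes them. At the default size the
#' oracle's Monte Carlo standard error is below 0.002.
#'
#' @param config a [dgp_config()].
#' @param oracle_n simulation size, default 1e6.
#' @param rng_seed seed for the oracle sample (independent of
#'   `config$rng_seed`).
#' @return List `true_tce`, `true_nde`, `true_nie`,
#'   `true_prop_mediated`, `means`, `oracle_n`, `method`.
#' @export
true_effects <- function(config, oracle_n = 1e6, rng_seed = 20260101L) {
  set.seed(derive_seed(rng_seed, "true_effects"))
  dat <- dgp_confounders(oracle_n)
  clip <- config$m_model$clip
  eps <- stats::rnorm(oracle_n, 0, config$m_model$residual_sd)
  m_under <- function(x) {
    score <- as.integer(pmin(pmax(
      round(dgp_m_latent_lp(config$m_model, x, dat) + eps),
      clip[1]), clip[2]))
    if (identical(config$y_model$mediator, "raw")) score
    else as.integer(score >= 56L)
  }
  m1 <- m_under(1)
  m0 <- m_under(0)
  mu <- c(mu_11 = mean(expit(dgp_y_lp(config$y_model, 1, m1, dat))),
          mu_00 = mean(expit(dgp_y_lp(config$y_model, 0, m0, dat))),
          mu_10 = mean(expit(dgp_y_lp(config$y_model, 1, m0, dat))))
  est <- decompose_effects(mu)
  list(true_tce = est$tce, true_nde = est$nde, true_nie = est$nie,
       true_prop_mediated = est$prop_mediated, means = mu,
       oracle_n = oracle_n,
       method = paste("direct simulation from the true structural models;",
                      "outcome probabilities averaged analytically"))
}

#' Inject completely-at-random missingness
#'
#' With probability `rate` per record, one analysis cell (chosen
#' uniformly among exposure, mediator, outcome and confounders) is set
#' missing, for exercising the listwise-exclusion pipeline.
#'
#' @param table participant table.
#' @param rate per-record missingness probability in `[0, 1)`.
#' @param rng_seed integer seed.
#' @return The table with NA cells; attribute `n_affected`.
#' @export
missingness_inject <- function(table, rate, rng_seed = 1L) {
  gc_assert(rate >= 0 && rate < 1, "rate must lie in [0, 1)")
  if (rate == 0) {
    attr(table, "n_affected") <- 0L
    return(table)
  }
  cols <- intersect(analysis_columns(
    c("maternal_age", "infant_age", "parity", "delivery_mode", "education",
      "employment", "assets", "hiv", "hps_high", "hsi_high")), names(table))
  set.seed(derive_seed(rng_seed, "missingness"))
  hit <- which(stats::runif(nrow(table)) < rate)
  for (i in hit) {
    col <- sample(cols, 1L)
    table[i, col] <- NA
  }
  attr(table, "n_affected") <- length(hit)
  table
}
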