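# Variable derivation: questionnaire responses -> analysis variables.
#
# The analysis variables are: a binary exposure (perceiving nurses as
# helpful "always" vs any less often), a mediator (breastfeeding
# self-efficacy, BSES-SF sum score 14-70, optionally split at a
# threshold), a binary outcome (exclusive breastfeeding), and a set of
# confounders (demographics, household assets, two health-literacy
# scales).

#' Dichotomise perceived nurse helpfulness
#'
#' The exposure item asks how often the clinic nurses are helpful on a
#' four-level ordinal scale. It is collapsed to 1 for "always" and 0 for
#' "sometimes", "seldom" or "never".
#'
#' @param nurse_helpful character vector with levels
#'   `"always"`, `"sometimes"`, `"seldom"`, `"never"` (case-insensitive).
#' @return Integer vector of 0/1 (NA preserved).
#' @export
#' @examples
#' binarize_exposure(c("always", "sometimes", "never"))
binarize_exposure <- function(nurse_helpful) {
  lev <- tolower(trimws(as.character(nurse_helpful)))
  ok <- lev %in% c("always", "sometimes", "seldom", "never") | is.na(lev)
  if (!all(ok)) {
    gc_stop(sprintf("unknown helpfulness level(s): %s",
                    paste(unique(lev[!ok]), collapse = ", ")),
            "gcompmed_validation_error")
  }
  out <- as.integer(lev == "always")
  out[is.na(lev)] <- NA_integer_
  out
}

#' Score the BSES-SF (breastfeeding self-efficacy, short form)
#'
#' Sums 14 Likert items, each scored 1 (not at all confident) to 5
#' (very confident); totals range 14-70, higher = more self-efficacy.
#'
#' @param items numeric vector of length 14, or a matrix/data frame with
#'   14 columns (one row per participant).
#' @return Integer total score(s) in `[14, 70]`.
#' @export
score_bses <- function(items) {
  m <- as.matrix(items)
  if (is.vector(items) || (is.null(dim(items)) && length(items) == 14L)) {
    m <- matrix(as.numeric(items), nrow = 1L)
  }
  gc_assert(ncol(m) == 14L,
            sprintf("BSES-SF needs exactly 14 items, got %d", ncol(m)))
  vals <- m[!is.na(m)]
  gc_assert(all(vals >= 1 & vals <= 5 & vals == floor(vals)),
            "BSES-SF items must be integers in [1, 5]")
  out <- as.integer(rowSums(m))
  if (is.null(dim(items)) && length(items) == 14L) out[1L] else out
}

#' Split a BSES-SF total into high/low self-efficacy
#'
#' Scores at or above the threshold (default 56, the study's reported
#' split point) count as high; "scored below 56" defines the low group,
#' so the boundary is inclusive on the high side.
#'
#' @param total integer total score(s) in `[14, 70]`.
#' @param threshold integer split point, default 56.
#' @return Integer 0/1 (1 = high self-efficacy).
#' @export
binarize_bses <- function(total, threshold = 56L) {
  vals <- total[!is.na(total)]
  gc_assert(all(vals >= 14 & vals <= 70),
            "BSES-SF total must lie in [14, 70]")
  out <- as.integer(total >= threshold)
  out[is.na(total)] <- NA_integer_
  out
}

#' Derive breastfeeding exclusivity
#'
#' A mother is exclusively breastfeeding iff she is currently
#' breastfeeding and has never given the newborn anything besides
#' breastmilk.
#'
#' @param currently_breastfeeding,ever_given_other logical (or 0/1,
#'   yes/no, true/false) vectors.
#' @return Integer 0/1; NA where either flag is missing.
#' @export
derive_exclusivity <- function(currently_breastfeeding, ever_given_other) {
  cb <- parse_flag(currently_breastfeeding, "currently_breastfeeding")
  ev <- parse_flag(ever_given_other, "ever_given_other")
  as.integer(cb & !ev)
}

#' Score one HLQ scale and dichotomise it
#'
#' Each Health Literacy Questionnaire scale used here has 4 items scored
#' 1 (strongly disagree) to 4 (strongly agree); the scale score is the
#' item mean and is "high" when the mean is at or above `cut`.
#'
#' @param items numeric vector of length 4, or matrix/data frame with 4
#'   columns.
#' @param cut high/low cut point on the mean, default 2.5.
#' @return A list with `mean` and `high` (0/1).
#' @export
score_hlq_scale <- function(items, cut = 2.5) {
  single <- is.null(dim(items)) && length(items) == 4L
  m <- if (single) matrix(as.numeric(items), nrow = 1L) else as.matrix(items)
  gc_assert(ncol(m) == 4L,
            sprintf("HLQ scale needs exactly 4 items, got %d", ncol(m)))
  vals <- m[!is.na(m)]
  gc_assert(all(vals >= 1 & vals <= 4 & vals == floor(vals)),
            "HLQ items must be integers in [1, 4]")
  mu <- rowMeans(m)
  high <- as.integer(mu >= cut)
  high[is.na(mu)] <- NA_integer_
  if (single) list(mean = mu[1L], high = high[1L]) else list(mean = mu, high = high)
}

#' Count household assets
#'
#' @param items logical (or coercible) vector of length 13, or a
#'   matrix/data frame with 13 columns.
#' @return Integer count(s) in `[0, 13]`.
#' @export
count_assets <- function(items) {
  single <- is.null(dim(items)) && length(items) == 13L
  m <- if (single) matrix(items, nrow = 1L) else as.matrix(items)
  gc_assert(ncol(m) == 13L,
            sprintf("asset inventory needs exactly 13 items, got %d", ncol(m)))
  flags <- matrix(parse_flag(as.vector(m), "asset item"), nrow = nrow(m))
  out <- as.integer(rowSums(flags))
  if (single) out[1L] else out
}

# Columns the fitted equations need; records missing any are dropped
# listwise before analysis.
analysis_columns <- function(confounders) {
  c("x_helpful", "bses_total", "m_bses_high", "y_exclusive", confounders)
}

#' Derive the analysis table from raw questionnaire data
#'
#' Applies the derivation rules column by column. Columns already present
#' in derived form (`x_helpful`, `bses_total`, `m_bses_high`,
#' `y_exclusive`, `hps_high`, `hsi_high`, `assets`) are passed through
#' unchanged; raw inputs (`nurse_helpful`, `bses_1..bses_14`,
#' `currently_breastfeeding` + `ever_given_other`, `hlq_hps_1..4`,
#' `hlq_hsi_1..4`, `asset_1..13`) are derived where the derived column is
#' absent. Records missing the exposure, mediator, outcome or any listed
#' confounder are excluded listwise, and the exclusions are tallied by
#' reason.
#'
#' @param raw data frame of raw and/or pre-derived columns.
#' @param confounders character vector of confounder column names that
#'   the analysis will adjust for (these must be complete for a record to
#'   be retained). Default: the study's confounder set present in `raw`.
#' @param bses_threshold split point for the mediator, default 56.
#' @param hlq_cut high/low cut for HLQ scale means, default 2.5.
#' @return A data frame of complete analysis records with attributes
#'   `exclusion_log` (named counts per reason, plus `n_input`/`n_retained`)
#'   and `derived_from` (per-variable provenance: "raw" or "passthrough").
#' @export
derive_variables <- function(raw, confounders = NULL,
                             bses_threshold = 56L, hlq_cut = 2.5) {
  df <- as.data.frame(raw, stringsAsFactors = FALSE)
  provenance <- c()

  derive_one <- function(target, raw_cols, fun) {
    if (target %in% names(df)) {
      provenance[target] <<- "passthrough"
    } else if (all(raw_cols %in% names(df))) {
      df[[target]] <<- fun(df[raw_cols])
      provenance[target] <<- "raw"
    }
    invisible(NULL)
  }

  derive_one("x_helpful", "nurse_helpful",
             function(d) binarize_exposure(d[[1L]]))
  derive_one("bses_total", paste0("bses_", 1:14), score_bses)
  if (!"m_bses_high" %in% names(df) && "bses_total" %in% names(df)) {
    df$m_bses_high <- binarize_bses(df$bses_total, bses_threshold)
    provenance["m_bses_high"] <- "raw"
  } else if ("m_bses_high" %in% names(df)) {
    provenance["m_bses_high"] <- "passthrough"
  }
  derive_one("y_exclusive", c("currently_breastfeeding", "ever_given_other"),
             function(d) derive_exclusivity(d[[1L]], d[[2L]]))
  derive_one("hps_high", paste0("hlq_hps_", 1:4),
             function(d) score_hlq_scale(d, cut = hlq_cut)$high)
  derive_one("hsi_high", paste0("hlq_hsi_", 1:4),
             function(d) score_hlq_scale(d, cut = hlq_cut)$high)
  derive_one("assets", paste0("asset_", 1:13), count_assets)

  if (is.null(confounders)) {
    confounders <- intersect(
      c("maternal_age", "infant_age", "parity", "delivery_mode",
        "education", "employment", "assets", "hiv", "hps_high", "hsi_high"),
      names(df))
  }
  need <- analysis_columns(confounders)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    gc_stop(sprintf("cannot derive required column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "gcompmed_validation_error")
  }
  if ("delivery_mode" %in% names(df) && is.character(df$delivery_mode)) {
    lev <- tolower(trimws(df$delivery_mode))
    bad <- !(lev %in% c("vaginal", "caesarean")) & !is.na(lev)
    gc_assert(!any(bad), "delivery_mode must be 'vaginal' or 'caesarean'")
    df$delivery_mode <- as.integer(lev == "caesarean")
  }

  # listwise exclusion, tallied by first missing column per record
  log <- c(n_input = nrow(df))
  keep <- rep(TRUE, nrow(df))
  for (col in need) {
    miss <- is.na(df[[col]]) & keep
    if (any(miss)) log[paste0("missing_", col)] <- sum(miss)
    keep <- keep & !miss
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  log["n_excluded"] <- nrow(df) - nrow(out)
  log["n_retained"] <- nrow(out)
  attr(out, "exclusion_log") <- as.list(log)
  attr(out, "derived_from") <- as.list(provenance)
  attr(out, "confounders") <- confounders
  out
}

#' Restrict to the repeat-visit subsample
#'
#' Keeps records whose second assessment happened on a different (later)
#' day than the first, and swaps in the second-visit mediator, outcome
#' and infant age columns (`bses_total_v2`, `y_exclusive_v2`,
#' `infant_age_v2`, with `visit2_days_after` giving the day gap).
#'
#' @param data derived analysis table with second-visit columns.
#' @param bses_threshold mediator split point, default 56.
#' @return The subsample with first-visit columns replaced by
#'   second-visit values; attribute `exclusion_log` counts the drops.
#' @export
select_repeat_visit <- function(data, bses_threshold = 56L) {
  need <- c("visit2_days_after", "bses_total_v2", "y_exclusive_v2",
            "infant_age_v2")
  gc_assert(all(need %in% names(data)),
            paste("repeat-visit columns required:",
                  paste(setdiff(need, names(data)), collapse = ", ")))
  gap <- data$visit2_days_after
  keep <- !is.na(gap) & gap > 0 &
    !is.na(data$bses_total_v2) & !is.na(data$y_exclusive_v2)
  out <- data[keep, , drop = FALSE]
  out$bses_total <- out$bses_total_v2
  out$m_bses_high <- binarize_bses(out$bses_total_v2, bses_threshold)
  out$y_exclusive <- out$y_exclusive_v2
  out$infant_age <- out$infant_age_v2
  rownames(out) <- NULL
  attr(out, "exclusion_log") <- list(
    n_input = nrow(data),
    no_distinct_repeat_visit = sum(!keep),
    n_retained = nrow(out))
  attr(out, "confounders") <- attr(data, "confounders")
  out
}
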