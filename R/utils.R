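#' @keywords internal
"_PACKAGE"

expit <- stats::plogis

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop with a classed condition so callers/tests can match on class.
gc_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "gcompmed_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

gc_assert <- function(cond, msg, class = "gcompmed_validation_error") {
  if (!isTRUE(cond)) gc_stop(msg, class)
  invisible(TRUE)
}

#' Derive a reproducible child seed from a master seed
#'
#' All stochastic stages (mediator simulation, bootstrap replicates, data
#' generation) draw their seeds from one master seed through this counter
#' scheme, so dropping a bootstrap replicate or reordering stages never
#' shifts another stage's random stream.
#'
#' @param master integer master seed.
#' @param ... stage labels (strings) and/or integer counters.
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483629 # largest prime < 2^31
  h <- as.double(master %% m)
  for (part in list(...)) {
    if (is.character(part)) {
      for (code in utf8ToInt(part)) h <- (h * 69621 + code) %% m
    } else {
      h <- (h * 48271 + as.double(part) %% m) %% m
    }
  }
  as.integer(h %% (m - 1L) + 1)
}

# Parse booleans given as 0/1, yes/no, true/false (case-insensitive).
parse_flag <- function(x, field = "flag") {
  if (is.logical(x)) return(x)
  key <- tolower(trimws(as.character(x)))
  map <- c("0" = FALSE, "1" = TRUE, "no" = FALSE, "yes" = TRUE,
           "false" = FALSE, "true" = TRUE)
  out <- unname(map[key])
  out[is.na(key)] <- NA
  bad <- !is.na(key) & !(key %in% names(map))
  if (any(bad)) {
    gc_stop(sprintf("cannot interpret %s value(s): %s", field,
                    paste(unique(key[bad]), collapse = ", ")),
            "gcompmed_validation_error")
  }
  out
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
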