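# Regression equations consumed by the G-computation: a linear model
# for the mediator and a logistic model for the outcome. Fitting is
# delegated to base R's least-squares and IRLS machinery
# (stats::lm.fit / stats::glm.fit); this file supplies the design
# handling, diagnostics and Wald summaries around them.

#' Specify one regression equation
#'
#' @param response response column name.
#' @param terms ordered character vector of predictor column names.
#' @param family `"gaussian_identity"` (linear) or `"binomial_logit"`
#'   (logistic).
#' @param include_intercept logical, default TRUE.
#' @return A `design_spec` object.
#' @export
design_spec <- function(response, terms,
                        family = c("gaussian_identity", "binomial_logit"),
                        include_intercept = TRUE) {
  family <- match.arg(family)
  terms <- as.character(terms)
  gc_assert(!anyDuplicated(terms), "design terms must be unique")
  gc_assert(!(response %in% terms), "response cannot appear among the terms")
  structure(list(response = response, terms = terms, family = family,
                 include_intercept = include_intercept),
            class = "design_spec")
}

# Build the model matrix for a design. Categorical columns (factor or
# character) are expanded to reference-coded indicators with the most
# frequent level as reference.
build_design_matrix <- function(design, data) {
  missing_cols <- setdiff(design$terms, names(data))
  if (length(missing_cols)) {
    gc_stop(sprintf("column(s) absent from data: %s",
                    paste(missing_cols, collapse = ", ")),
            "gcompmed_validation_error")
  }
  n <- nrow(data)
  cols <- if (design$include_intercept)
    list(`(Intercept)` = rep(1, n)) else list()
  coding <- list()
  for (term in design$terms) {
    v <- data[[term]]
    if (is.character(v) || is.factor(v)) {
      v <- as.character(v)
      tab <- sort(table(v), decreasing = TRUE)
      ref <- names(tab)[1L]
      coding[[term]] <- list(reference = ref, levels = names(tab))
      for (lev in setdiff(names(tab), ref)) {
        cols[[paste0(term, lev)]] <- as.numeric(v == lev)
      }
    } else {
      cols[[term]] <- as.numeric(v)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  attr(X, "coding") <- coding
  X
}

#' Fit a regression equation
#'
#' Gaussian-identity designs are fit by QR least squares; binomial-logit
#' designs by iteratively reweighted least squares with convergence
#' declared at the usual deviance tolerance. Possible separation in a
#' logistic fit (fitted probabilities pinned at 0/1 with runaway
#' coefficients) is surfaced through `converged = FALSE`, never
#' silently accepted. Rank-deficient designs are an error naming the
#' collinear columns.
#'
#' @param design a [design_spec()].
#' @param data data frame containing the response and term columns.
#' @return A `fitted_model`: coefficients, `residual_sd` (gaussian
#'   only), `vcov`, `converged`, `n_obs`, `loglik`, `family`.
#' @export
med_fit <- function(design, data) {
  gc_assert(design$response %in% names(data),
            sprintf("response column '%s' absent from data", design$response))
  X <- build_design_matrix(design, data)
  y <- as.numeric(data[[design$response]])
  gc_assert(!anyNA(X) && !anyNA(y), "fit data contain missing values")
  n <- nrow(X); p <- ncol(X)
  gc_assert(n > p, sprintf("need more observations (%d) than parameters (%d)",
                           n, p))

  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    gc_stop(sprintf("design is rank deficient; collinear column(s): %s",
                    paste(bad, collapse = ", ")),
            "gcompmed_fit_error")
  }

  if (design$family == "gaussian_identity") {
    fit <- stats::lm.fit(X, y)
    beta <- fit$coefficients
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / (n - p)
    XtXinv <- chol2inv(qr.R(qrX))
    vcov <- sigma2 * XtXinv
    loglik <- -0.5 * n * (log(2 * pi) + log(rss / n) + 1)
    converged <- TRUE
    residual_sd <- sqrt(sigma2)
  } else {
    gc_assert(all(y %in% c(0, 1)), "binomial response must be 0/1")
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-10,
                                                  maxit = 100)))
    beta <- fit$coefficients
    mu <- fit$fitted.values
    separated <- any(mu < 1e-8 | mu > 1 - 1e-8) && max(abs(beta)) > 15
    converged <- isTRUE(fit$converged) && !separated
    w <- mu * (1 - mu)
    info <- crossprod(X * sqrt(w))
    vcov <- tryCatch(chol2inv(chol(info)), error = function(e) {
      matrix(NA_real_, p, p)
    })
    loglik <- sum(y * log(pmax(mu, 1e-12)) +
                    (1 - y) * log(pmax(1 - mu, 1e-12)))
    residual_sd <- NULL
  }
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(
    list(coefficients = stats::setNames(as.numeric(beta), colnames(X)),
         residual_sd = residual_sd, vcov = vcov, converged = converged,
         n_obs = n, loglik = loglik, family = design$family,
         design = design, coding = attr(X, "coding")),
    class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("fitted_model (%s), n = %d, converged: %s\n",
              x$family, x$n_obs, x$converged))
  print(round(x$coefficients, 4))
  if (!is.null(x$residual_sd))
    cat(sprintf("residual sd: %.4f\n", x$residual_sd))
  invisible(x)
}

# JSON-ready summary of a fitted equation.
model_as_list <- function(model) {
  list(family = model$family,
       coefficients = as.list(model$coefficients),
       residual_sd = model$residual_sd,
       converged = model$converged,
       n_obs = model$n_obs,
       loglik = model$loglik)
}

#' Evaluate the linear predictor for new records
#'
#' Returns `intercept + sum(beta_j * x_j)`; for a logistic model this is
#' on the logit scale.
#'
#' @param model a `fitted_model`.
#' @param newdata data frame with all term columns.
#' @return Numeric vector of linear predictors.
#' @export
predict_linear <- function(model, newdata) {
  X <- build_design_matrix(model$design, newdata)
  gc_assert(identical(colnames(X), names(model$coefficients)),
            "newdata columns do not match the fitted design")
  drop(X %*% model$coefficients)
}

#' Wald test for one coefficient
#'
#' Uses the estimated coefficient covariance; gaussian fits use the t
#' reference with the residual degrees of freedom, logistic fits the
#' normal reference. A non-converged model still reports the statistics
#' but carries `warning = TRUE`.
#'
#' @param model a `fitted_model`.
#' @param term coefficient name (a design term or expanded indicator).
#' @param level confidence level, default 0.95.
#' @return List with `beta`, `se`, `statistic`, `p`, `ci` and `warning`.
#' @export
coefficient_test <- function(model, term, level = 0.95) {
  gc_assert(term %in% names(model$coefficients),
            sprintf("term '%s' not in the model", term))
  beta <- model$coefficients[[term]]
  se <- sqrt(model$vcov[term, term])
  if (model$family == "gaussian_identity") {
    df <- model$n_obs - length(model$coefficients)
    stat <- if (se > 0) beta / se else NA_real_
    p <- if (se > 0) 2 * stats::pt(-abs(stat), df) else NA_real_
    q <- stats::qt((1 + level) / 2, df)
  } else {
    stat <- if (se > 0) beta / se else NA_real_
    p <- if (se > 0) 2 * stats::pnorm(-abs(stat)) else NA_real_
    q <- stats::qnorm((1 + level) / 2)
  }
  ci <- if (se > 0) c(beta - q * se, beta + q * se) else c(beta, beta)
  list(beta = beta, se = se, statistic = stat, p = p, ci = ci,
       warning = !model$converged)
}
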