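#' Unpenalized maximum-likelihood fit of a sub-model
#'
#' Fits the generalized linear model restricted to the columns in `support`,
#' with an intercept and no penalty, and returns the maximal log-likelihood
#' that every information criterion consumes. Refitting without penalty is
#' essential when candidates come from a LASSO path: the shrunken LASSO
#' coefficients put the log-likelihood below its maximum by an amount that
#' grows with the penalty, which would corrupt likelihood-ratio comparisons
#' between supports fitted at different regularization strengths.
#'
#' For the linear family the fit is ordinary least squares with the error
#' variance profiled at its maximum-likelihood value, so that
#' `loglik = -(n/2) * (log(2 * pi * RSS / n) + 1)` and differences of
#' log-likelihoods equal the classical likelihood-ratio statistic
#' `(n/2) * log(RSS0 / RSS1)`. For the logistic family the Bernoulli
#' likelihood is maximized by iteratively reweighted least squares; under
#' complete separation the optimizer stops at its iteration cap and the fit
#' is returned with `converged = FALSE` rather than dropped, so that such
#' supports still compete in selection.
#'
#' @param x Numeric design matrix (n rows, p columns) with column names used
#'   as stable identifiers; unnamed columns are labelled `X1..Xp`.
#' @param y Outcome: numeric for `family = "linear"`, 0/1 for
#'   `family = "logistic"`.
#' @param family `"linear"` or `"logistic"`.
#' @param support Columns to include: integer indices or column names.
#'   Empty for the intercept-only model.
#' @return An object of class `ic_fit`: list with `support` (column names),
#'   `intercept`, `coefficients` (named), `loglik`, `converged`, `family`,
#'   `n`.
#' @examples
#' x <- cbind(a = c(0, 1, 2, 3))
#' fit_glm_support(x, c(0, 1, 1, 2), "linear", "a")
#' @export
fit_glm_support <- function(x, y, family = c("linear", "logistic"),
                            support = integer()) {
  family <- match.arg(family)
  x <- as_design_matrix(x)
  y <- check_outcome(y, family, nrow(x))
  idx <- resolve_support(x, support)
  if (length(idx) + 1 >= nrow(x)) {
    stop("support too large: need |support| + 1 < n for an unpenalized fit.",
         call. = FALSE)
  }
  xs <- x[, idx, drop = FALSE]
  n <- nrow(x)
  if (family == "linear") {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, xs), y)
    if (fit$rank < ncol(xs) + 1) {
      dropped <- colnames(xs)[is.na(fit$coefficients[-1])]
      stop("singular design in support {", paste(dropped, collapse = ", "),
           "}: collinear columns.", call. = FALSE)
    }
    rss <- sum(fit$residuals^2)
    loglik <- -(n / 2) * (log(2 * pi * rss / n) + 1)
    coefs <- fit$coefficients
    converged <- TRUE
  } else {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(`(Intercept)` = 1, xs), y,
                     family = stats::binomial(),
                     control = list(maxit = 100))
    )
    if (fit$rank < ncol(xs) + 1) {
      dropped <- colnames(xs)[is.na(fit$coefficients[-1])]
      stop("singular design in support {", paste(dropped, collapse = ", "),
           "}: collinear columns.", call. = FALSE)
    }
    mu <- fit$fitted.values
    loglik <- sum(y * log(mu) + (1 - y) * log1p(-mu))
    coefs <- fit$coefficients
    converged <- fit$converged
  }
  structure(
    list(
      support = colnames(xs),
      intercept = unname(coefs[1]),
      coefficients = coefs[-1],
      loglik = loglik,
      converged = converged,
      family = family,
      n = n
    ),
    class = "ic_fit"
  )
}

#' @export
print.ic_fit <- function(x, ...) {
  cat("<ic_fit> ", x$family, " model, support {",
      paste(x$support, collapse = ", "), "}, logLik = ",
      formatC(x$loglik, digits = 6, format = "g"),
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}

#' @method glance ic_fit
#' @export
glance.ic_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    size = length(x$support),
    logLik = x$loglik,
    converged = x$converged,
    nobs = x$n
  )
}

#' @method tidy ic_fit
#' @export
tidy.ic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$support),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' Log-likelihood difference between two nested fits
#'
#' `delta_loglik(full, reduced)` returns `full$loglik - reduced$loglik`, the
#' half likelihood-ratio statistic whose doubled value is asymptotically
#' chi-squared(1) when the models differ by one parameter and the reduced
#' model is true. Tiny negative values from floating-point noise are clipped
#' to zero; non-nested supports are an error.
#'
#' @param full,reduced `ic_fit` objects with `reduced$support` a subset of
#'   `full$support`.
#' @return A single non-negative number.
#' @export
delta_loglik <- function(full, reduced) {
  stopifnot(inherits(full, "ic_fit"), inherits(reduced, "ic_fit"))
  if (!all(reduced$support %in% full$support)) {
    stop("models are not nested: the reduced support must be contained in ",
         "the full support.", call. = FALSE)
  }
  d <- full$loglik - reduced$loglik
  if (d < -1e-8) {
    stop("full-model log-likelihood is below the reduced model's by ",
         format(-d), "; the fits are not maximal.", call. = FALSE)
  }
  max(d, 0)
}

# --- fast single-variable scans --------------------------------------------
# Exact per-column maximal log-likelihoods of all one-variable models (plus
# the null model), used by the null scan where fitting p separate models via
# lm.fit/glm.fit would dominate run time. Both are exact maximum-likelihood
# computations, tested against fit_glm_support().

# Linear: with an intercept, RSS_j = Syy * (1 - r_j^2) with r_j = cor(y, x_j),
# so the profiled log-likelihood is a closed form in the correlation.
scan_loglik_linear <- function(x, y) {
  n <- length(y)
  syy <- sum((y - mean(y))^2)
  r <- suppressWarnings(as.vector(stats::cor(y, x)))
  r[is.na(r)] <- 0 # zero-variance columns carry no signal
  rss <- syy * (1 - r^2)
  ll <- -(n / 2) * (log(2 * pi * rss / n) + 1)
  list(loglik = ll, null_loglik = -(n / 2) * (log(2 * pi * syy / n) + 1))
}

# Logistic: per-column Newton iterations on (intercept, slope), all columns
# advanced simultaneously. Identical to IRLS; steps are capped to keep
# (near-)separated columns finite, mirroring glm.fit's iteration cap.
scan_loglik_logistic <- function(x, y, maxit = 60L, tol = 1e-10) {
  n <- length(y)
  p <- ncol(x)
  ybar <- mean(y)
  if (ybar <= 0 || ybar >= 1) {
    stop("logistic outcome is constant; no model can be fit.", call. = FALSE)
  }
  a <- rep(stats::qlogis(ybar), p)
  b <- numeric(p)
  sy <- sum(y)
  xty <- as.vector(crossprod(x, y))
  for (it in seq_len(maxit)) {
    eta <- sweep(x * rep(b, each = n), 2, a, "+")
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    g1 <- sy - colSums(mu)
    g2 <- xty - colSums(x * mu)
    h11 <- colSums(w)
    h12 <- colSums(x * w)
    h22 <- colSums(x * x * w)
    det <- h11 * h22 - h12^2
    det[det < 1e-12] <- 1e-12
    da <- (h22 * g1 - h12 * g2) / det
    db <- (h11 * g2 - h12 * g1) / det
    # cap step length for stability under (near-)separation
    step <- pmax(abs(da), abs(db))
    shrink <- ifelse(step > 2, 2 / step, 1)
    a <- a + da * shrink
    b <- b + db * shrink
    if (max(abs(g1), abs(g2)) < tol) break
  }
  eta <- sweep(x * rep(b, each = n), 2, a, "+")
  ll <- unname(colSums(y * stats::plogis(eta, log.p = TRUE) +
                         (1 - y) * stats::plogis(-eta, log.p = TRUE)))
  null_ll <- n * (ybar * log(ybar) + (1 - ybar) * log1p(-ybar))
  list(loglik = ll, null_loglik = null_ll)
}

scan_loglik <- function(x, y, family) {
  if (family == "linear") scan_loglik_linear(x, y) else scan_loglik_logistic(x, y)
}

# --- input helpers ---------------------------------------------------------

as_design_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix or data frame.", call. = FALSE)
  }
  if (anyNA(x)) stop("`x` contains missing values.", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  x
}

check_outcome <- function(y, family, n) {
  y <- as.numeric(y)
  if (length(y) != n) stop("`y` length must match nrow(x).", call. = FALSE)
  if (anyNA(y)) stop("`y` contains missing values.", call. = FALSE)
  if (n < 2) stop("need at least 2 observations.", call. = FALSE)
  if (family == "logistic" && !all(y %in% c(0, 1))) {
    stop("logistic outcome must contain only 0 and 1.", call. = FALSE)
  }
  y
}

resolve_support <- function(x, support) {
  if (length(support) == 0) return(integer())
  if (is.character(support)) {
    idx <- match(support, colnames(x))
    if (anyNA(idx)) {
      stop("unknown columns: ", paste(support[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
  } else {
    idx <- as.integer(support)
    if (any(idx < 1) || any(idx > ncol(x))) {
      stop("support indices out of range.", call. = FALSE)
    }
  }
  sort(unique(idx))
}

# Split a data frame into design matrix and outcome, the data-frame-first
# entry used by select_variables() and the CLI.
split_outcome <- function(data, outcome) {
  if (!is.data.frame(data)) stop("`data` must be a data frame.", call. = FALSE)
  if (!outcome %in% names(data)) {
    stop("outcome column `", outcome, "` not found in `data`.", call. = FALSE)
  }
  y <- data[[outcome]]
  x <- as_design_matrix(data[setdiff(names(data), outcome)])
  list(x = x, y = y)
}
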