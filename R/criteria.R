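#' Criterion specifications
#'
#' An information criterion scores a candidate support A as
#' `-2 * loglik(A) + penalty(|A|)`. `criterion()` builds a specification
#' holding the criterion name, the (n, p) context it is evaluated in, and its
#' constants. `|A|` counts candidate regressors only: the intercept (and, in
#' linear models, the error variance) is present in every model and excluded
#' from the size, so that nested one-variable comparisons reduce to
#' likelihood-ratio tests of one degree of freedom.
#'
#' Per-variable weights (linear penalties):
#' * `AIC`: 2
#' * `BIC`: `log(n)`
#' * `RIC`: `2 * log(p)`
#' * `mAIC`: `2 + 2 * log(p / c)`, constant `c` (default 1/2)
#' * `mBIC`: `log(n) + 2 * log(p / E)`, constant `E` (default 4)
#' * `EAIC`: `2 * critical_bound(p, alpha)`, the multiplicity-corrected
#'   likelihood-ratio threshold at FWER target `alpha` (default 0.05)
#'
#' `EBIC` is the one non-linear penalty:
#' `log(n) * size + 2 * gamma * lchoose(p, size)` with `gamma` in `[0, 1]`
#' (default 1); its combinatorial term vanishes at sizes 0 and p.
#'
#' @param name One of `"AIC"`, `"BIC"`, `"RIC"`, `"mAIC"`, `"mBIC"`,
#'   `"EBIC"`, `"EAIC"`.
#' @param n,p Observation and candidate-regressor counts. May be left `NULL`
#'   at construction when unknown; selection functions fill them from the
#'   data before any penalty is evaluated.
#' @param alpha EAIC family-wise error target in (0, 1).
#' @param c,E,gamma Constants of the mAIC, mBIC and EBIC.
#' @return An object of class `ic_criterion`.
#' @examples
#' criterion("EAIC", n = 1000, p = 100, alpha = 0.05)
#' criterion("BIC", n = 1000)
#' @export
criterion <- function(name = c("EAIC", "AIC", "BIC", "RIC", "mAIC", "mBIC",
                               "EBIC"),
                      n = NULL, p = NULL,
                      alpha = 0.05, c = 0.5, E = 4, gamma = 1) {
  name <- match.arg(name)
  check_alpha(alpha)
  if (c <= 0) stop("`c` must be positive.", call. = FALSE)
  if (E <= 0) stop("`E` must be positive.", call. = FALSE)
  if (gamma < 0) stop("`gamma` must be non-negative.", call. = FALSE)
  constants <- switch(name,
    EAIC = list(alpha = alpha),
    mAIC = list(c = c),
    mBIC = list(E = E),
    EBIC = list(gamma = gamma),
    list()
  )
  structure(
    list(name = name, n = n, p = p, constants = constants),
    class = "ic_criterion"
  )
}

#' @export
print.ic_criterion <- function(x, ...) {
  consts <- if (length(x$constants)) {
    paste0(" (", paste(names(x$constants), unlist(x$constants), sep = " = ",
                       collapse = ", "), ")")
  } else ""
  ctx <- paste0("n = ", x$n %||% "?", ", p = ", x$p %||% "?")
  cat("<ic_criterion> ", x$name, consts, " [", ctx, "]\n", sep = "")
  invisible(x)
}

#' @export
format.ic_criterion <- function(x, ...) {
  consts <- if (length(x$constants)) {
    paste0("(", paste(names(x$constants), unlist(x$constants), sep = "=",
                      collapse = ","), ")")
  } else ""
  paste0(x$name, consts)
}

# Fill missing (n, p) context from the data; never overwrite values the user
# set explicitly.
with_context <- function(spec, n = NULL, p = NULL) {
  stopifnot(inherits(spec, "ic_criterion"))
  if (is.null(spec$n)) spec$n <- n
  if (is.null(spec$p)) spec$p <- p
  spec
}

#' Per-variable weight of the extended AIC
#'
#' `2 * critical_bound(p, alpha)`: twice the threshold that `p` implicit
#' likelihood-ratio tests must clear for an asymptotic family-wise error rate
#' of `alpha`. At `alpha = alpha_ric(p)` it equals the RIC weight
#' `2 * log(p)`; at `alpha = alpha_bic_equiv(n, p)` it equals the BIC weight
#' `log(n)`.
#'
#' @inheritParams alpha_ric
#' @param alpha Family-wise error target in (0, 1).
#' @return Numeric weights.
#' @export
eaic_weight <- function(p, alpha) {
  2 * critical_bound(p, alpha)
}

#' Penalty of a criterion at a given support size
#'
#' @param spec An [criterion()] specification whose (n, p) context is set
#'   where the criterion needs it.
#' @param size Number of candidate regressors in the support, `0 <= size <= p`.
#' @return The penalty value; 0 at `size = 0` for every criterion.
#' @examples
#' ic_penalty(criterion("AIC"), 3)
#' ic_penalty(criterion("EAIC", p = 100, alpha = 0.05), 1)
#' @export
ic_penalty <- function(spec, size) {
  stopifnot(inherits(spec, "ic_criterion"))
  name <- spec$name
  n <- spec$n
  p <- spec$p
  needs_n <- name %in% c("BIC", "mBIC", "EBIC")
  needs_p <- name %in% c("RIC", "mAIC", "mBIC", "EBIC", "EAIC")
  if (needs_n && is.null(n)) {
    stop("criterion ", name, " needs the observation count `n`.",
         call. = FALSE)
  }
  if (needs_p && is.null(p)) {
    stop("criterion ", name, " needs the candidate count `p`.", call. = FALSE)
  }
  if (!is.null(p) && any(size > p)) {
    stop("`size` cannot exceed the number of candidate regressors `p`.",
         call. = FALSE)
  }
  if (any(size < 0)) stop("`size` must be non-negative.", call. = FALSE)
  if (name == "EBIC") {
    gamma <- spec$constants$gamma
    return(log(n) * size + 2 * gamma * lchoose(p, size))
  }
  w <- switch(name,
    AIC  = 2,
    BIC  = log(n),
    RIC  = 2 * log(p),
    mAIC = 2 + 2 * log(p / spec$constants$c),
    mBIC = log(n) + 2 * log(p / spec$constants$E),
    EAIC = eaic_weight(p, spec$constants$alpha)
  )
  w * size
}

#' Score of a support under a criterion
#'
#' `-2 * loglik + ic_penalty(spec, size)`. For two nested supports differing
#' by one variable the score difference is `weight - 2 * delta_l`, so
#' minimizing the criterion between them is exactly a likelihood-ratio test
#' at threshold `weight / 2`.
#'
#' @inheritParams ic_penalty
#' @param loglik Maximal unpenalized log-likelihood of the support.
#' @return The criterion value.
#' @export
ic_score <- function(spec, loglik, size) {
  -2 * loglik + ic_penalty(spec, size)
}

#' Overview table of criterion weights and coincidence levels
#'
#' For a given (n, p) context, tabulates the per-variable weight of every
#' linear-penalty criterion together with the analytic levels at which the
#' EAIC coincides with the RIC, the mAIC and the BIC, and the
#' simplest-form level `alpha_null_cancel()`.
#'
#' @param n,p Observation and candidate-regressor counts.
#' @param alpha EAIC levels to tabulate.
#' @param c,E mAIC and mBIC constants.
#' @return A tibble with one row per criterion; coincidence levels are
#'   attached as the `coincidence` attribute and printed by the CLI.
#' @export
criteria_table <- function(n, p, alpha = c(0.5, 0.05), c = 0.5, E = 4) {
  specs <- c(
    list(criterion("AIC", n = n, p = p),
         criterion("BIC", n = n, p = p),
         criterion("RIC", n = n, p = p),
         criterion("mAIC", n = n, p = p, c = c),
         criterion("mBIC", n = n, p = p, E = E)),
    lapply(alpha, function(a) criterion("EAIC", n = n, p = p, alpha = a))
  )
  out <- tibble::tibble(
    criterion = vapply(specs, format, character(1)),
    weight = vapply(specs, ic_penalty, numeric(1), size = 1)
  )
  attr(out, "coincidence") <- tibble::tibble(
    level = c("alpha0 (simplest form)", "alpha_RIC(p)", "alpha_mAIC(p, c)",
              "alpha_BIC_equiv(n, p)"),
    alpha = c(alpha_null_cancel(), alpha_ric(p), alpha_maic(p, c),
              alpha_bic_equiv(n, p))
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
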