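#' Asymptotic distribution of the likelihood-ratio half-statistic
#'
#' Under the smaller of two nested models differing by one parameter, twice the
#' difference of maximal log-likelihoods, `2 * delta_l`, is asymptotically
#' chi-squared with one degree of freedom (Wilks), so `delta_l` itself follows
#' a Gamma(1/2, 1) law. `half_chisq_cdf()` evaluates its cumulative
#' distribution function \eqn{F(x) = P(\chi^2_1 \le 2x) = \mathrm{erf}(\sqrt
#' x)}, the building block of every family-wise error computation in this
#' package.
#'
#' @param x Non-negative numeric vector of log-likelihood differences.
#' @param lower.tail,log.p As in [stats::pchisq()]. `log.p = TRUE` with
#'   `lower.tail = FALSE` retains full precision in the extreme upper tail,
#'   which matters when the result is raised to a large power.
#' @return Probabilities (or log-probabilities), same length as `x`.
#' @seealso [family_max_cdf()], [critical_bound()]
#' @examples
#' half_chisq_cdf(1)          # P(Delta l <= 1), approx 0.8427
#' 1 - half_chisq_cdf(1)      # per-test level implied by the AIC, 0.1573
#' @export
half_chisq_cdf <- function(x, lower.tail = TRUE, log.p = FALSE) {
  if (any(x < 0)) {
    stop("`x` must be non-negative: a difference of maximal log-likelihoods ",
         "of nested models cannot be negative.", call. = FALSE)
  }
  stats::pchisq(2 * x, df = 1, lower.tail = lower.tail, log.p = log.p)
}

#' Multiplicity-corrected critical bound for q likelihood-ratio tests
#'
#' The threshold
#' \deqn{x_{q,\alpha} = \log q - \tfrac12 \log\log q - \log(-\log(1-\alpha))
#'   - \tfrac12 \log\pi}
#' has the property that rejecting each of `q` independent one-parameter
#' likelihood-ratio tests when its half-statistic exceeds it gives an
#' asymptotic family-wise error rate of `alpha` as `q` grows. It is the
#' per-variable half-penalty of the extended AIC with `q` set to the number of
#' candidate regressors.
#'
#' At \eqn{\alpha_0 = 1 - e^{-1/\sqrt\pi} \approx 0.43118} the last two terms
#' cancel and the bound reduces to \eqn{\log q - \tfrac12 \log\log q}.
#'
#' @param q Number of implicit tests (in selection, the proxy is the number of
#'   candidate regressors `p`). Must be at least 2; `q = 2` is accepted with a
#'   warning because `log log q` is then negative.
#' @param alpha Target family-wise error rate, in (0, 1).
#' @return Numeric vector of critical bounds, recycled over `q` and `alpha`.
#' @examples
#' critical_bound(100, 0.05)
#' critical_bound(100, alpha_null_cancel()) # = log(100) - log(log(100))/2
#' @export
critical_bound <- function(q, alpha) {
  check_alpha(alpha)
  if (any(q < 2)) {
    stop("`q` must be at least 2.", call. = FALSE)
  }
  if (any(q < 3)) {
    warning("`q` < 3 gives a negative log(log(q)) term; the bound is ",
            "returned but the asymptotic FWER interpretation is unreliable.",
            call. = FALSE)
  }
  log(q) - 0.5 * log(log(q)) - log(-log1p(-alpha)) - 0.5 * log(pi)
}

#' The level at which the critical bound takes its simplest form
#'
#' Returns \eqn{\alpha_0 = 1 - e^{-1/\sqrt\pi} \approx 0.43118}, the
#' family-wise error level at which the \eqn{-\log(-\log(1-\alpha))} and
#' \eqn{-\tfrac12\log\pi} terms of the critical bound cancel, so that
#' \eqn{x_{q,\alpha_0} = \log q - \tfrac12\log\log q}.
#'
#' @return A single number.
#' @export
alpha_null_cancel <- function() {
  -expm1(-1 / sqrt(pi))
}

#' CDF of the maximum of q independent likelihood-ratio half-statistics
#'
#' \eqn{F_q(x) = F(x)^q}, the asymptotic distribution function of
#' \eqn{\max(\Delta l_1, \dots, \Delta l_q)} for independent tests. Computed
#' in log space so that values remain accurate for `q` up to 1e6 and beyond,
#' where `1 - F(x)` underflows naive arithmetic.
#'
#' @param x Non-negative threshold(s).
#' @param q Number of independent tests; `q = 0` returns 1 (empty product).
#' @return Probabilities in `[0, 1]`.
#' @export
family_max_cdf <- function(x, q) {
  if (any(q < 0)) stop("`q` must be a non-negative count.", call. = FALSE)
  # log F(x) from the upper tail keeps precision when F(x) is close to 1
  log_f <- half_chisq_cdf(x, lower.tail = TRUE, log.p = TRUE)
  exp(q * log_f)
}

#' Asymptotic family-wise error rate of thresholding q tests at x
#'
#' \eqn{1 - F(x)^q}: the limiting probability that at least one of `q`
#' independent likelihood-ratio half-statistics exceeds `x` under the global
#' null. With `x = critical_bound(q, alpha)` this converges to `alpha` as `q`
#' grows.
#'
#' @inheritParams family_max_cdf
#' @return Probabilities in `[0, 1]`.
#' @examples
#' asymptotic_fwer(1, 1)  # one test at threshold 1: 0.1573
#' asymptotic_fwer(1e4, critical_bound(1e4, 0.05))
#' @export
asymptotic_fwer <- function(q, x) {
  log_f <- half_chisq_cdf(x, lower.tail = TRUE, log.p = TRUE)
  -expm1(q * log_f)
}

#' Level at which the EAIC coincides with the risk inflation criterion
#'
#' The EAIC weight \eqn{2 x_{p,\alpha}} equals the RIC weight \eqn{2\log p}
#' exactly when \eqn{\log\log p + 2\log(-\log(1-\alpha)) + \log\pi = 0},
#' i.e. at \eqn{\alpha_{RIC}(p) = 1 - e^{-1/\sqrt{\pi\log p}}}. This is the
#' implicit family-wise test level of the RIC; it decreases very slowly in p.
#'
#' @param p Number of candidate regressors, greater than 1.
#' @return Levels in (0, 1), strictly decreasing in `p`.
#' @examples
#' alpha_ric(100) # approx 0.231
#' @export
alpha_ric <- function(p) {
  check_p(p)
  -expm1(-1 / sqrt(pi * log(p)))
}

#' Level at which the EAIC coincides with the modified AIC
#'
#' The mAIC has weight \eqn{2\log p - 2\log c + 2}; the EAIC matches it at
#' \eqn{\alpha_{mAIC}(p, c) = 1 - e^{-(c/e)/\sqrt{\pi\log p}}}. The usual
#' recommendation for the constant is `c = 1/2`.
#'
#' @inheritParams alpha_ric
#' @param c Positive mAIC constant (default 1/2).
#' @return Levels in (0, 1).
#' @examples
#' alpha_maic(100)   # approx 0.0472
#' alpha_maic(1e4)   # approx 0.0336
#' @export
alpha_maic <- function(p, c = 0.5) {
  check_p(p)
  if (any(c <= 0)) stop("`c` must be positive.", call. = FALSE)
  -expm1(-(c / exp(1)) / sqrt(pi * log(p)))
}

#' mAIC constant matching a target EAIC level
#'
#' Inverse of [alpha_maic()] in `c`:
#' \eqn{c_{EAIC}(p, \alpha) = -e\,\sqrt{\pi \log p}\,\log(1-\alpha)}, the mAIC
#' constant whose weight equals the EAIC weight at level `alpha`.
#'
#' @inheritParams alpha_ric
#' @param alpha Target level in (0, 1).
#' @return Positive constants; `alpha_maic(p, c_eaic(p, a)) == a` up to
#'   rounding.
#' @export
c_eaic <- function(p, alpha) {
  check_p(p)
  check_alpha(alpha)
  -exp(1) * sqrt(pi * log(p)) * log1p(-alpha)
}

#' Level at which the EAIC is mathematically equivalent to the BIC
#'
#' Solves \eqn{2 x_{p,\alpha} = \log n} for `alpha` in closed form by
#' inverting the critical bound:
#' \eqn{\log(-\log(1-\alpha)) = \log p - \tfrac12\log\log p -
#' \tfrac12\log\pi - \tfrac12\log n}. At this level the two criteria rank all
#' models identically.
#'
#' @param n Number of observations (at least 2).
#' @param p Number of candidate regressors (greater than 1).
#' @return Levels in (0, 1).
#' @examples
#' alpha_bic_equiv(452914, 1692) # approx 0.406
#' @export
alpha_bic_equiv <- function(n, p) {
  check_p(p)
  if (any(n < 2)) stop("`n` must be at least 2.", call. = FALSE)
  log_mlog <- log(p) - 0.5 * log(log(p)) - 0.5 * log(pi) - 0.5 * log(n)
  a <- -expm1(-exp(log_mlog))
  if (any(a >= 1) || any(a <= 0)) {
    stop("no solution in (0, 1) at double precision: log(n) is too ",
         if (any(a >= 1)) "small" else "large", " relative to p.",
         call. = FALSE)
  }
  a
}

#' Approximate family-wise error rate of BIC-based selection
#'
#' When the compared models are sparse (\eqn{|A| \ll n/\log n}), the FWER of
#' selecting among the p one-variable extensions of the true model by BIC is
#' approximately \eqn{1 - e^{-p/\sqrt{\pi n \log(n)/2}}}. The exact
#' counterpart is \eqn{1 - F(\tfrac12\log n)^p}. For p growing like a power
#' of n above 1 this tends to 1: the BIC does not bound the FWER in high
#' dimension.
#'
#' @param n Number of observations (at least 3).
#' @param p Number of candidate regressors (0 allowed, giving 0).
#' @param exact If `TRUE`, return the exact expression `1 - F(log(n)/2)^p`
#'   instead of the sparse-model approximation.
#' @return Probabilities in `[0, 1]`.
#' @export
bic_fwer_approx <- function(n, p, exact = FALSE) {
  if (any(n < 3)) stop("`n` must be at least 3.", call. = FALSE)
  if (any(p < 0)) stop("`p` must be a non-negative count.", call. = FALSE)
  if (exact) {
    asymptotic_fwer(p, 0.5 * log(n))
  } else {
    -expm1(-p / sqrt(pi * n * log(n) / 2))
  }
}

#' Monte-Carlo check of the null family-wise error bound
#'
#' Samples `reps` families of `q` independent half-statistics
#' \eqn{\Delta l_i \sim \chi^2_1 / 2} and estimates the probability that the
#' maximum exceeds `critical_bound(q, alpha)`. Serves as a simulation oracle
#' for [asymptotic_fwer()]: the estimate should sit within binomial noise of
#' the analytic value.
#'
#' @param q Number of tests per family.
#' @param alpha Target level.
#' @param reps Number of Monte-Carlo families (at least 100).
#' @param seed Integer seed; the estimate is reproducible given the seed.
#' @return A tibble with the estimate, its binomial standard error, the
#'   analytic asymptotic value and the inputs.
#' @export
mc_null_fwer <- function(q, alpha, reps = 1e4, seed = 1L) {
  if (reps < 100) stop("`reps` must be at least 100.", call. = FALSE)
  x <- critical_bound(q, alpha)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  # max of q iid chi^2_1/2 draws compared with the bound, per family
  hits <- vapply(seq_len(reps), function(i) {
    max(stats::rchisq(q, df = 1)) / 2 > x
  }, logical(1))
  est <- mean(hits)
  tibble::tibble(
    q = q, alpha = alpha, reps = reps,
    fwer_mc = est,
    se = sqrt(est * (1 - est) / reps),
    fwer_asymptotic = asymptotic_fwer(q, x)
  )
}

# --- input checks ----------------------------------------------------------

check_alpha <- function(alpha) {
  if (any(alpha <= 0) || any(alpha >= 1)) {
    stop("`alpha` must lie strictly between 0 and 1.", call. = FALSE)
  }
  invisible(alpha)
}

check_p <- function(p) {
  if (any(p <= 1)) {
    stop("`p` must exceed 1 (log(p) must be positive).", call. = FALSE)
  }
  invisible(p)
}

# Save/restore .Random.seed so seeded helpers do not disturb the caller's RNG
# stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
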