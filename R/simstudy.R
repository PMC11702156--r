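#' Draw a Gaussian design with Toeplitz (AR(1)) column correlation
#'
#' Rows are i.i.d. multivariate normal with mean zero and covariance
#' `Sigma[i, j] = rho^|i - j|`, generated by the AR(1) recursion
#' `X[, j] = rho * X[, j - 1] + sqrt(1 - rho^2) * e[, j]` in O(np) time, so
#' designs with p = 1e4 stay tractable. `rho = 0` gives i.i.d. standard
#' normal columns.
#'
#' @param n,p Dimensions of the design.
#' @param rho Base correlation in `[0, 1)`.
#' @param seed Optional integer seed (the caller's RNG state is preserved).
#' @return An n x p numeric matrix with columns `X1..Xp`.
#' @export
draw_design <- function(n, p, rho = 0, seed = NULL) {
  if (abs(rho) >= 1) stop("`rho` must satisfy |rho| < 1.", call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  x <- matrix(stats::rnorm(n * p), n, p)
  if (rho != 0) {
    s <- sqrt(1 - rho^2)
    for (j in 2:p) x[, j] <- rho * x[, j - 1] + s * x[, j]
  }
  colnames(x) <- paste0("X", seq_len(p))
  x
}

#' Empirical signal-to-noise ratio of a generalized linear model
#'
#' The ratio of the empirical variance (divisor n - 1) of the conditional
#' means `E[Y_i | X]` over the empirical mean of the conditional variances
#' `Var(Y_i | X)`. In the linear model the conditional variance is 1; in the
#' logistic model it is `mu_i * (1 - mu_i)` with
#' `mu = plogis(intercept + X %*% beta)`. A larger SNR means each active
#' variable's effect is more visible against the outcome noise; in the linear
#' family the SNR scales exactly as the square of the coefficient scale.
#'
#' @param x Design matrix.
#' @param beta Coefficient vector of length `ncol(x)`.
#' @param intercept Intercept (default 0).
#' @param family `"linear"` or `"logistic"`.
#' @return A single non-negative number.
#' @export
empirical_snr <- function(x, beta, intercept = 0,
                          family = c("linear", "logistic")) {
  family <- match.arg(family)
  eta <- as.vector(x %*% beta) + intercept
  if (family == "linear") {
    stats::var(eta)
  } else {
    mu <- stats::plogis(eta)
    denom <- mean(mu * (1 - mu))
    if (denom <= 0) {
      stop("degenerate logistic model: all conditional variances are zero.",
           call. = FALSE)
    }
    stats::var(mu) / denom
  }
}

#' Rescale raw coefficients to hit a target empirical SNR
#'
#' Given raw coefficients `beta` (nonzero on the active set), finds the scale
#' `k` (and, for the logistic family, the intercept `b0`) such that
#' `empirical_snr(x, k * beta, b0, family)` equals `target_snr`. The linear
#' case is closed-form (`k = sqrt(target / snr(beta))`, intercept 0, since
#' the linear SNR is exactly quadratic in the scale). The logistic case
#' solves the two-equation system \{SNR = target, mean(mu) = 1/2\} for
#' `(k, b0)` by damped Newton iterations with a finite-difference Jacobian;
#' the balance constraint `mean(mu) = 1/2` pins down the intercept.
#'
#' @inheritParams empirical_snr
#' @param target_snr Desired empirical SNR, positive.
#' @param tol Relative tolerance on the achieved SNR (default 1e-8).
#' @return List with `k`, `intercept`, `beta` (the rescaled vector) and
#'   `achieved_snr`.
#' @export
calibrate_coefficients <- function(x, beta, target_snr,
                                   family = c("linear", "logistic"),
                                   tol = 1e-8) {
  family <- match.arg(family)
  if (target_snr <= 0) stop("`target_snr` must be positive.", call. = FALSE)
  s <- as.vector(x %*% beta)
  if (all(s == 0)) stop("`beta` carries no signal.", call. = FALSE)
  if (family == "linear") {
    k <- sqrt(target_snr / stats::var(s))
    out <- list(k = k, intercept = 0, beta = k * beta,
                achieved_snr = stats::var(k * s))
    return(out)
  }
  # logistic: damped Newton on (k, b0)
  resid <- function(th) {
    mu <- stats::plogis(th[2] + th[1] * s)
    denom <- mean(mu * (1 - mu))
    c(stats::var(mu) / denom - target_snr, mean(mu) - 0.5)
  }
  th <- c(2 * sqrt(target_snr / stats::var(s)), 0) # small-signal linearization
  f <- resid(th)
  for (it in seq_len(200)) {
    if (max(abs(f[1]) / target_snr, abs(f[2])) < tol) break
    h <- pmax(abs(th), 1) * 1e-6
    jac <- cbind((resid(th + c(h[1], 0)) - f) / h[1],
                 (resid(th + c(0, h[2])) - f) / h[2])
    step <- tryCatch(solve(jac, -f), error = function(e) NULL)
    if (is.null(step)) {
      stop("SNR calibration failed: singular Jacobian at k = ", th[1],
           ", intercept = ", th[2], call. = FALSE)
    }
    lam <- 1
    repeat {
      cand <- th + lam * step
      if (cand[1] > 0) {
        fc <- resid(cand)
        if (sum(fc^2) < sum(f^2) || lam < 1e-6) break
      }
      lam <- lam / 2
      if (lam < 1e-12) break
    }
    th <- th + lam * step
    f <- resid(th)
  }
  if (max(abs(f[1]) / target_snr, abs(f[2])) >= 1e-6) {
    stop("SNR calibration did not converge: residuals ",
         paste(format(f), collapse = ", "), " at k = ", th[1],
         ", intercept = ", th[2], call. = FALSE)
  }
  list(k = th[1], intercept = th[2], beta = th[1] * beta,
       achieved_snr = target_snr + f[1])
}

#' Simulate an outcome from a generalized linear model
#'
#' Linear family: `y = intercept + x %*% beta + e` with standard normal
#' errors (conditional variance 1, matching the SNR convention). Logistic
#' family: `y ~ Bernoulli(plogis(intercept + x %*% beta))`.
#'
#' @inheritParams empirical_snr
#' @param seed Optional integer seed (the caller's RNG state is preserved).
#' @return Numeric outcome vector of length `nrow(x)`.
#' @export
draw_outcome <- function(x, beta, intercept = 0,
                         family = c("linear", "logistic"), seed = NULL) {
  family <- match.arg(family)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  eta <- as.vector(x %*% beta) + intercept
  n <- nrow(x)
  if (family == "linear") {
    eta + stats::rnorm(n)
  } else {
    stats::rbinom(n, 1, stats::plogis(eta))
  }
}

#' Per-replicate error and recovery metrics of a selection
#'
#' Compares a selected support with the true active set: `fp_event` flags at
#' least one selected inactive variable (the family-wise error event),
#' `fdp` is the false-discovery proportion (0 when nothing is selected),
#' `tp` the number of recovered active variables, and `sensitivity`
#' `tp / n_active`.
#'
#' @param selected Character vector of selected column names.
#' @param active Character vector of truly active column names.
#' @param n_active Size of the true active set (defaults to
#'   `length(active)`).
#' @return One-row tibble.
#' @export
selection_metrics <- function(selected, active, n_active = length(active)) {
  fp <- length(setdiff(selected, active))
  tp <- length(intersect(selected, active))
  tibble::tibble(
    fp_event = fp > 0,
    fdp = fp / max(1, length(selected)),
    tp = tp,
    sensitivity = if (n_active > 0) tp / n_active else NA_real_
  )
}

# Counter-based per-replicate seeds: adding settings or replicates never
# perturbs earlier replicates, and every seed stays a valid 32-bit integer.
rep_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 + i * 16807) %%
               2147483647) + 1L
}

#' Null-hypothesis study: FWER of the EAIC single-variable scan
#'
#' Simulates `reps` datasets in which the outcome is independent of all
#' regressors (standard normal outcome for the linear family, Bernoulli(0.5)
#' for the logistic one; Gaussian design with Toeplitz correlation `rho`),
#' runs [null_scan()] with the EAIC at level `alpha` on each, and reports the
#' proportion of replicates in which a non-null model is selected - the
#' estimated family-wise error rate, which the EAIC is designed to hold at
#' `alpha` for large n and p. Correlation screening (fraction 0.9) is applied
#' when `p >= 10^4`, where scanning every column is wasteful.
#'
#' @param family `"linear"` or `"logistic"`.
#' @param n,p,rho Design dimensions and Toeplitz base correlation.
#' @param alpha EAIC family-wise error target.
#' @param reps Number of simulated datasets (default 1000).
#' @param seed Master seed; per-replicate seeds are derived from it by a
#'   counter scheme, so results are reproducible and extensible.
#' @param screen_fraction Correlation-screening fraction, or `NULL` for the
#'   default rule (0.9 when `p >= 10^4`, none otherwise).
#' @return One-row tibble of class `eaic_study` with the setting, the FWER
#'   estimate, its binomial standard error and the analytic asymptotic value.
#' @export
run_null_study <- function(family = c("linear", "logistic"), n, p, rho = 0,
                           alpha = 0.05, reps = 1000, seed = 1L,
                           screen_fraction = NULL) {
  family <- match.arg(family)
  if (is.null(screen_fraction) && p >= 1e4) screen_fraction <- 0.9
  spec <- criterion("EAIC", n = n, p = p, alpha = alpha)
  x_bound <- critical_bound(p, alpha)
  hits <- logical(reps)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  for (i in seq_len(reps)) {
    set.seed(rep_seed(seed, i))
    x <- draw_design(n, p, rho)
    y <- if (family == "linear") stats::rnorm(n) else stats::rbinom(n, 1, 0.5)
    sel <- null_scan(x, y, family, spec, screen_fraction = screen_fraction)
    hits[i] <- length(sel$support) > 0
  }
  est <- mean(hits)
  out <- tibble::tibble(
    study = "null", family = family, n = n, p = p, rho = rho,
    snr = NA_real_, method = format(spec),
    fwer = est, fwer_se = sqrt(est * (1 - est) / reps),
    fdr = NA_real_, mean_tp = NA_real_, sensitivity = NA_real_,
    reps = reps, fwer_asymptotic = asymptotic_fwer(p, x_bound)
  )
  class(out) <- c("eaic_study", class(out))
  out
}

#' Default method set of the full-procedure study
#'
#' The six information criteria compared in the full study: AIC, BIC, EBIC
#' (gamma = 1), mAIC (c = 1/2), mBIC (E = 4), and the EAIC at levels 0.5 and
#' 0.05. The oracle selector is added separately by [run_full_study()].
#'
#' @return Named list of [criterion()] specifications.
#' @export
study_methods <- function() {
  list(
    criterion("AIC"),
    criterion("BIC"),
    criterion("EBIC", gamma = 1),
    criterion("mAIC", c = 0.5),
    criterion("mBIC", E = 4),
    criterion("EAIC", alpha = 0.5),
    criterion("EAIC", alpha = 0.05)
  )
}

#' Full-procedure study: LASSO path + unpenalized refit + criterion
#'
#' Simulates `reps` datasets with `n_active` truly active variables whose
#' coefficients are drawn with random signs and magnitudes uniform on
#' (0.25, 1), then rescaled so the empirical signal-to-noise ratio equals
#' `snr` ([calibrate_coefficients()]). On each dataset the LASSO path is
#' computed once, every distinct support on it is refit without penalty
#' once, and each method picks its support; family-wise error (any inactive
#' variable selected), false-discovery proportion and sensitivity are
#' averaged over replicates. The oracle selector (first support of size at
#' least `n_active`) is included as a benchmark of what the path itself can
#' deliver.
#'
#' @inheritParams run_null_study
#' @param snr Target empirical signal-to-noise ratio, positive.
#' @param n_active Number of active variables (default 10).
#' @param methods List of [criterion()] specifications (default
#'   [study_methods()]).
#' @param include_oracle Add the oracle selector (default `TRUE`).
#' @param dfmax Maximum support size on the LASSO path (default 100).
#' @return Tibble of class `eaic_study`, one row per method, with FWER, FDR,
#'   mean true positives, sensitivity and Monte-Carlo standard errors.
#' @export
run_full_study <- function(family = c("linear", "logistic"), n, p, rho = 0,
                           snr, n_active = 10, reps = 1000, seed = 1L,
                           methods = study_methods(), include_oracle = TRUE,
                           dfmax = 100) {
  family <- match.arg(family)
  stopifnot(n_active <= p, snr > 0)
  methods <- lapply(methods, with_context, n = n, p = p)
  labels <- vapply(methods, format, character(1))
  if (include_oracle) labels <- c(labels, "oracle")
  records <- vector("list", reps)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  max_redraws <- max(1, ceiling(0.01 * reps))
  redraws <- 0
  for (i in seq_len(reps)) {
    sub <- 0L
    repeat {
      res <- tryCatch(
        full_study_replicate(family, n, p, rho, snr, n_active,
                             rep_seed(seed, i * 1009L + sub), methods,
                             include_oracle, dfmax),
        error = function(e) e
      )
      if (!inherits(res, "error")) break
      redraws <- redraws + 1
      sub <- sub + 1L
      if (redraws > max_redraws) {
        stop("too many failed replicates (last error: ",
             conditionMessage(res), ")", call. = FALSE)
      }
      warning("replicate ", i, " redrawn: ", conditionMessage(res),
              call. = FALSE)
    }
    records[[i]] <- res
  }
  all_rec <- dplyr::bind_rows(records)
  out <- all_rec |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      fwer = mean(.data$fp_event),
      fwer_se = sqrt(mean(.data$fp_event) * (1 - mean(.data$fp_event)) /
                       dplyr::n()),
      fdr = mean(.data$fdp),
      mean_tp = mean(.data$tp),
      sensitivity = mean(.data$sensitivity),
      reps = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      study = "full", family = family, n = n, p = p, rho = rho, snr = snr,
      .before = 1
    ) |>
    dplyr::arrange(match(.data$method, labels))
  class(out) <- c("eaic_study", class(out))
  out
}

full_study_replicate <- function(family, n, p, rho, snr, n_active, seed,
                                 methods, include_oracle, dfmax) {
  set.seed(seed)
  x <- draw_design(n, p, rho)
  active_idx <- sample.int(p, n_active)
  raw <- numeric(p)
  raw[active_idx] <- stats::runif(n_active, 0.25, 1) *
    sample(c(-1, 1), n_active, replace = TRUE)
  cal <- calibrate_coefficients(x, raw, snr, family)
  y <- draw_outcome(x, cal$beta, cal$intercept, family)
  active <- colnames(x)[active_idx]
  path <- lasso_supports(x, y, family, dfmax = dfmax)
  fits <- lapply(path$supports, function(s) {
    tryCatch(fit_glm_support(x, y, family, s), error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no support on the path could be refit.")
  rows <- lapply(methods, function(spec) {
    sel <- score_fits(fits[ok], which(ok), spec)
    dplyr::mutate(selection_metrics(sel$support, active, n_active),
                  method = format(spec), .before = 1)
  })
  if (include_oracle) {
    orc <- suppressWarnings(oracle_select(path, n_active))
    rows <- c(rows, list(
      dplyr::mutate(selection_metrics(orc, active, n_active),
                    method = "oracle", .before = 1)
    ))
  }
  dplyr::bind_rows(rows)
}

#' Plot study metrics against the signal-to-noise ratio
#'
#' For results of [run_full_study()] accumulated over an SNR grid, draws one
#' line per method on a log-scaled SNR axis, faceted by setting when several
#' (family, n, p, rho) combinations are present.
#'
#' @param object A tibble of class `eaic_study` (rows from one or more
#'   studies).
#' @param metric One of `"fwer"`, `"fdr"`, `"sensitivity"`, `"mean_tp"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eaic_study
#' @export
autoplot.eaic_study <- function(object, metric = c("fwer", "fdr",
                                                   "sensitivity", "mean_tp"),
                                ...) {
  metric <- match.arg(metric)
  df <- dplyr::filter(object, !is.na(.data[[metric]]))
  gg <- ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$snr, y = .data[[metric]],
                 colour = .data$method, group = .data$method)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "empirical SNR", y = metric)
  if (dplyr::n_distinct(paste(df$family, df$n, df$p, df$rho)) > 1) {
    gg <- gg + ggplot2::facet_wrap(~ family + n + p + rho,
                                   labeller = ggplot2::label_both)
  }
  gg
}
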