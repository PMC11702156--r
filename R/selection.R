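#' Candidate supports from a LASSO regularization path
#'
#' Runs coordinate-descent LASSO (squared loss for the linear family,
#' Bernoulli deviance for the logistic one) over a geometric grid of 100
#' regularization values starting at the smallest value that zeroes every
#' coefficient, and extracts the sequence of distinct supports as the
#' penalty relaxes. Columns are standardized internally; supports are
#' deduplicated preserving first appearance; the path is truncated at the
#' first support exceeding `dfmax` variables. The empty support is always the
#' first candidate.
#'
#' @inheritParams fit_glm_support
#' @param dfmax Maximum support size kept on the path (default 100).
#' @param nlambda Number of grid points (default 100).
#' @return An object of class `ic_path`: list with `supports` (list of
#'   character vectors of column names, first element empty), `source`
#'   (`"lasso"`), and `p`.
#' @export
lasso_supports <- function(x, y, family = c("linear", "logistic"),
                           dfmax = 100, nlambda = 100) {
  family <- match.arg(family)
  x <- as_design_matrix(x)
  y <- check_outcome(y, family, nrow(x))
  if (stats::var(y) == 0) {
    stop("outcome is constant; the LASSO path is undefined.", call. = FALSE)
  }
  glm_family <- if (family == "linear") "gaussian" else "binomial"
  fit <- glmnet::glmnet(x, y, family = glm_family, nlambda = nlambda,
                        dfmax = dfmax)
  beta <- fit$beta # p x nlambda sparse matrix
  supports <- list(character())
  seen <- c("")
  for (k in seq_len(ncol(beta))) {
    nz <- which(beta[, k] != 0)
    if (length(nz) > dfmax) break
    key <- paste(nz, collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      supports <- c(supports, list(colnames(x)[nz]))
    }
  }
  new_ic_path(supports, source = "lasso", p = ncol(x))
}

#' Build a path family from explicit supports
#'
#' Wraps an explicit list of candidate supports in the structure that
#' [select_by_criterion()] consumes, deduplicating while preserving order.
#'
#' @param supports List of character or integer vectors of column
#'   identifiers.
#' @param p Number of candidate regressors the supports are drawn from.
#' @return An `ic_path` object with `source = "explicit"`.
#' @export
path_family <- function(supports, p) {
  supports <- lapply(supports, function(s) {
    if (is.numeric(s)) as.character(s) else as.character(s)
  })
  keys <- vapply(supports, function(s) paste(sort(s), collapse = ","),
                 character(1))
  new_ic_path(supports[!duplicated(keys)], source = "explicit", p = p)
}

new_ic_path <- function(supports, source, p) {
  structure(list(supports = supports, source = source, p = p),
            class = "ic_path")
}

#' @export
print.ic_path <- function(x, ...) {
  sizes <- lengths(x$supports)
  cat("<ic_path> ", length(x$supports), " candidate supports (",
      x$source, "), sizes ", min(sizes), "..", max(sizes), ", p = ", x$p,
      "\n", sep = "")
  invisible(x)
}

#' Select the support minimizing an information criterion
#'
#' Refits every candidate support on the path without penalty
#' ([fit_glm_support()]), scores each as `-2 * loglik + penalty(size)`
#' under `spec`, and returns the minimizer. Ties go to the smaller support,
#' then to the earlier path position. A support whose refit fails (for
#' example through collinearity) is skipped with a warning.
#'
#' @param path An `ic_path` from [lasso_supports()] or [path_family()].
#' @inheritParams fit_glm_support
#' @param spec An [criterion()] specification; its (n, p) context is filled
#'   from the data when missing.
#' @return An object of class `ic_selection`: list with `method` (criterion
#'   label), `support` (chosen column names), `fit` (the chosen `ic_fit`),
#'   and `table`, a tibble of all candidates (path position, size, loglik,
#'   score, chosen flag).
#' @export
select_by_criterion <- function(path, x, y, family = c("linear", "logistic"),
                                spec = criterion("EAIC")) {
  family <- match.arg(family)
  stopifnot(inherits(path, "ic_path"))
  x <- as_design_matrix(x)
  spec <- with_context(spec, n = nrow(x), p = ncol(x))
  fits <- vector("list", length(path$supports))
  ok <- logical(length(fits))
  for (i in seq_along(path$supports)) {
    fits[[i]] <- tryCatch(
      fit_glm_support(x, y, family, path$supports[[i]]),
      error = function(e) {
        warning("skipping support {",
                paste(path$supports[[i]], collapse = ", "), "}: ",
                conditionMessage(e), call. = FALSE)
        NULL
      }
    )
    ok[i] <- !is.null(fits[[i]])
  }
  if (!any(ok)) stop("no candidate support could be fit.", call. = FALSE)
  score_fits(fits[ok], which(ok), spec)
}

# Shared scorer: given already-refit candidates, build the selection object.
# Splitting this out lets the study drivers refit each support once and score
# it under several criteria.
score_fits <- function(fits, positions, spec) {
  sizes <- vapply(fits, function(f) length(f$support), integer(1))
  logliks <- vapply(fits, function(f) f$loglik, numeric(1))
  scores <- ic_score(spec, logliks, sizes)
  # argmin with ties to smaller support, then earlier path position
  ord <- order(scores, sizes, positions)
  best <- ord[1]
  tab <- tibble::tibble(
    position = positions,
    size = sizes,
    support = vapply(fits, function(f) paste(f$support, collapse = ","),
                     character(1)),
    loglik = logliks,
    score = scores,
    chosen = seq_along(fits) == best
  )
  structure(
    list(
      method = format(spec),
      spec = spec,
      support = fits[[best]]$support,
      fit = fits[[best]],
      table = tab
    ),
    class = "ic_selection"
  )
}

#' @export
print.ic_selection <- function(x, ...) {
  cat("<ic_selection> ", x$method, ": chose ", length(x$support),
      " variable(s)", sep = "")
  if (length(x$support)) {
    cat(" {", paste(x$support, collapse = ", "), "}", sep = "")
  }
  cat(", score ", formatC(min(x$table$score), digits = 6, format = "g"),
      " over ", nrow(x$table), " candidates\n", sep = "")
  invisible(x)
}

#' @method tidy ic_selection
#' @export
tidy.ic_selection <- function(x, ...) x$table

#' @method glance ic_selection
#' @export
glance.ic_selection <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_candidates = nrow(x$table),
    size = length(x$support),
    loglik = x$fit$loglik,
    score = x$table$score[x$table$chosen]
  )
}

#' Score profile of a selection along the candidate path
#'
#' Plots each candidate's criterion score against its support size,
#' highlighting the chosen support.
#'
#' @param object An `ic_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ic_selection
#' @export
autoplot.ic_selection <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$size, y = .data$score)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "support size", y = object$method,
                  title = paste("Criterion profile:", object$method))
}

#' Oracle selector: first support of at least k variables
#'
#' The benchmark rule that uses knowledge of the true number of active
#' variables: it picks the first support on the path with at least `k`
#' variables. If the path never reaches size `k` the last support is
#' returned with a warning.
#'
#' @param path An `ic_path`.
#' @param k True number of active variables (default 10).
#' @return Character vector of chosen column names.
#' @export
oracle_select <- function(path, k = 10) {
  stopifnot(inherits(path, "ic_path"))
  sizes <- lengths(path$supports)
  hit <- which(sizes >= k)
  if (length(hit) == 0) {
    warning("no support on the path reaches size ", k,
            "; returning the last support.", call. = FALSE)
    return(path$supports[[length(path$supports)]])
  }
  path$supports[[hit[1]]]
}

#' Correlation screening of candidate columns
#'
#' Keeps the columns whose absolute Pearson correlation with the outcome is
#' at least `fraction` of the maximal absolute correlation across columns.
#' Used by the null scan at very large p, where fitting every one-variable
#' model is wasteful: the maximal likelihood-ratio statistic can only come
#' from columns with near-maximal correlation.
#'
#' @inheritParams fit_glm_support
#' @param fraction Retention threshold in (0, 1]; `fraction = 1` keeps only
#'   the argmax column(s).
#' @return Character vector of retained column names.
#' @export
univariate_screen <- function(x, y, fraction = 0.9) {
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1].", call. = FALSE)
  }
  x <- as_design_matrix(x)
  r <- abs(suppressWarnings(as.vector(stats::cor(y, x))))
  r[is.na(r)] <- 0
  colnames(x)[r >= fraction * max(r) - 1e-12]
}

#' Null scan: the intercept-only model against every one-variable model
#'
#' Minimizes a criterion over the family made of the null model and all
#' single-variable models. For a linear-penalty criterion this is exactly the
#' multiple likelihood-ratio test that rejects the null when the maximal
#' half-statistic exceeds `weight / 2`; with the EAIC the weight is the
#' multiplicity-corrected bound, so the probability of a non-null selection
#' under a global null approaches the chosen `alpha`. Per-column maximal
#' log-likelihoods are computed by exact closed form (linear) or vectorized
#' Newton iterations (logistic); both agree with [fit_glm_support()] to
#' numerical precision.
#'
#' @inheritParams fit_glm_support
#' @param spec An [criterion()] specification.
#' @param screen_fraction Optional correlation-screening fraction: when set,
#'   only columns passing [univariate_screen()] are scanned. The criterion's
#'   `p` context stays at the full column count.
#' @return An `ic_selection`; its `table` has one row for the null model and
#'   one per scanned column.
#' @export
null_scan <- function(x, y, family = c("linear", "logistic"),
                      spec = criterion("EAIC"), screen_fraction = NULL) {
  family <- match.arg(family)
  x <- as_design_matrix(x)
  y <- check_outcome(y, family, nrow(x))
  spec <- with_context(spec, n = nrow(x), p = ncol(x))
  cols <- colnames(x)
  if (!is.null(screen_fraction)) {
    cols <- univariate_screen(x, y, screen_fraction)
  }
  sc <- scan_loglik(x[, cols, drop = FALSE], y, family)
  logliks <- c(sc$null_loglik, sc$loglik)
  sizes <- c(0L, rep(1L, length(cols)))
  scores <- ic_score(spec, logliks, sizes)
  ord <- order(scores, sizes, seq_along(scores))
  best <- ord[1]
  tab <- tibble::tibble(
    position = seq_along(scores),
    size = sizes,
    support = c("", cols),
    loglik = logliks,
    score = scores,
    chosen = seq_along(scores) == best
  )
  chosen_support <- if (best == 1) character() else cols[best - 1]
  fit <- list(
    support = chosen_support,
    loglik = logliks[best],
    family = family,
    converged = TRUE,
    n = nrow(x)
  )
  class(fit) <- "ic_fit"
  structure(
    list(method = format(spec), spec = spec, support = chosen_support,
         fit = fit, table = tab),
    class = "ic_selection"
  )
}

#' Data-frame-first variable selection with the LASSO path and a criterion
#'
#' The complete procedure: extract the sequence of candidate supports from a
#' LASSO regularization path, refit each support by unpenalized maximum
#' likelihood, and return the support minimizing the chosen information
#' criterion.
#'
#' @param data Data frame holding the outcome column and the candidate
#'   regressors (all numeric).
#' @param outcome Name of the outcome column.
#' @inheritParams fit_glm_support
#' @inheritParams select_by_criterion
#' @inheritParams lasso_supports
#' @return An `ic_selection`; `tidy()` gives the per-candidate score table,
#'   `glance()` a one-row summary.
#' @examples
#' set.seed(1)
#' d <- as.data.frame(matrix(rnorm(100 * 20), 100, 20))
#' d$y <- d$V1 * 2 + rnorm(100)
#' sel <- select_variables(d, "y", family = "linear",
#'                         spec = criterion("EAIC", alpha = 0.05))
#' sel$support
#' @export
select_variables <- function(data, outcome = "y",
                             family = c("linear", "logistic"),
                             spec = criterion("EAIC"), dfmax = 100) {
  family <- match.arg(family)
  parts <- split_outcome(data, outcome)
  path <- lasso_supports(parts$x, parts$y, family, dfmax = dfmax)
  select_by_criterion(path, parts$x, parts$y, family, spec)
}
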