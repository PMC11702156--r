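#' Load and validate an experiment configuration
#'
#' Reads a YAML or JSON configuration for the command-line drivers and fills
#' in defaults (`alpha = 0.05`, `c = 0.5`, `E = 4`, `gamma = 1`,
#' `dfmax = 100`, `reps = 1000`, `seed = 1`). Unknown keys are rejected so
#' that typos fail loudly rather than silently running a default.
#'
#' Recognised keys: `data` (CSV path), `outcome` (column name), `family`,
#' `criterion`, `alpha`, `c`, `E`, `gamma`, `dfmax`, `n`, `p`, `rho`, `snr`,
#' `n_active`, `reps`, `seed`, `screen_fraction`, `methods`, `output`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of class `eaic_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(cfg)) stop("config must be a mapping.", call. = FALSE)
  allowed <- c("data", "outcome", "family", "criterion", "alpha", "c", "E",
               "gamma", "dfmax", "n", "p", "rho", "snr", "n_active", "reps",
               "seed", "screen_fraction", "methods", "output")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  defaults <- list(outcome = "y", family = "linear", criterion = "EAIC",
                   alpha = 0.05, c = 0.5, E = 4, gamma = 1, dfmax = 100,
                   rho = 0, n_active = 10, reps = 1000, seed = 1L)
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  }
  if (!cfg$family %in% c("linear", "logistic")) {
    stop("config `family` must be \"linear\" or \"logistic\".", call. = FALSE)
  }
  valid_names <- c("AIC", "BIC", "RIC", "mAIC", "mBIC", "EBIC", "EAIC")
  if (!cfg$criterion %in% valid_names) {
    stop("unknown criterion name: ", cfg$criterion, call. = FALSE)
  }
  if (!is.null(cfg$methods) && !all(unlist(cfg$methods) %in%
                                      c(valid_names, "oracle"))) {
    stop("config `methods` contains unknown criterion names.", call. = FALSE)
  }
  structure(cfg, class = c("eaic_config", "list"))
}

#' Criterion specification from a configuration
#'
#' @param cfg An `eaic_config`.
#' @return An [criterion()] object built from the config's `criterion` name
#'   and constants.
#' @export
config_criterion <- function(cfg) {
  criterion(cfg$criterion, alpha = cfg$alpha, c = cfg$c, E = cfg$E,
            gamma = cfg$gamma)
}

#' Write study metrics to a tidy CSV
#'
#' One row per (setting, method) with the stable column order
#' `study, family, n, p, rho, snr, method, fwer, fwer_se, fdr, mean_tp,
#' sensitivity, reps`; numeric columns are written at 6 significant digits so
#' repeated runs give byte-identical files. An empty collection writes the
#' header only.
#'
#' @param metrics A tibble of study rows ([run_null_study()],
#'   [run_full_study()]), or a list of them.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  if (is.list(metrics) && !is.data.frame(metrics)) {
    metrics <- dplyr::bind_rows(metrics)
  }
  cols <- c("study", "family", "n", "p", "rho", "snr", "method", "fwer",
            "fwer_se", "fdr", "mean_tp", "sensitivity", "reps")
  if (nrow(metrics) == 0) {
    metrics <- tibble::as_tibble(stats::setNames(
      rep(list(logical()), length(cols)), cols
    ))
  } else {
    missing <- setdiff(cols, names(metrics))
    for (m in missing) metrics[[m]] <- NA
    metrics <- metrics[cols]
    num <- vapply(metrics, is.numeric, logical(1))
    metrics[num] <- lapply(metrics[num], signif, digits = 6)
  }
  utils::write.csv(metrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
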