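#' Run configuration for the decision pipeline
#'
#' Bundles every tunable of the pipeline with its documented default.
#' `w1 = NULL` requests the 95%-satisfaction calibration
#' `w1 = ln(20)/N(first observed year)` at replay time.
#'
#' @param w1 Satisfaction rate, or `NULL` for calibration.
#' @param w2 Ex situ preference discount in (0, 1]; default 2/3.
#' @param px Ex situ success probability; default 0.75.
#' @param horizon_percentile Extinction-time percentile defining the
#'   horizon; default 0.99.
#' @param horizon_cap Maximum horizon in years; `NULL` = automatic
#'   (`max(5 * observed span, 100)`).
#' @param n_rate_nodes Nodes for the decline-rate discretization; default
#'   201.
#' @param slope_dist `"normal"` (default) or `"t"`.
#' @param belief_variant `"conjugate"` (default) or `"as_printed"`.
#' @param clamp `"floor"` (default) or `"raw"`.
#' @param reference `"last_observed"` (default) or `"fitted"`.
#' @param fit_window Minimum observations before the first decision year;
#'   default 3.
#' @param seed Integer seed for any randomized step (`NULL` = leave RNG
#'   alone).
#' @param verbosity 0 (quiet), 1 (progress), 2 (debug).
#' @return An object of class `"run_config"` (named list).
#' @export
run_config <- function(w1 = NULL, w2 = 2 / 3, px = 0.75,
                       horizon_percentile = 0.99, horizon_cap = NULL,
                       n_rate_nodes = 201L,
                       slope_dist = c("normal", "t"),
                       belief_variant = c("conjugate", "as_printed"),
                       clamp = c("floor", "raw"),
                       reference = c("last_observed", "fitted"),
                       fit_window = 3L, seed = NULL, verbosity = 1L) {
  cfg <- list(
    w1 = w1, w2 = w2, px = px,
    horizon_percentile = horizon_percentile,
    horizon_cap = horizon_cap,
    n_rate_nodes = as.integer(n_rate_nodes),
    slope_dist = match.arg(slope_dist),
    belief_variant = match.arg(belief_variant),
    clamp = match.arg(clamp),
    reference = match.arg(reference),
    fit_window = as.integer(fit_window),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    verbosity = as.integer(verbosity)
  )
  # reuse value_params validation for the value-function scalars
  value_params(cfg$w1, cfg$w2, cfg$px)
  if (!(cfg$horizon_percentile > 0 && cfg$horizon_percentile < 1))
    stop("horizon_percentile must be in (0, 1)", call. = FALSE)
  if (cfg$n_rate_nodes < 1L) stop("n_rate_nodes must be >= 1", call. = FALSE)
  if (cfg$fit_window < 3L) stop("fit_window must be >= 3", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (ln in config_lines(x)) cat(" ", ln, "\n")
  invisible(x)
}

# key=value echo of the effective settings; used in output headers.
config_lines <- function(cfg) {
  fmt <- function(v) {
    if (is.null(v)) "auto" else as.character(v)
  }
  vapply(names(cfg), function(k) sprintf("%s=%s", k, fmt(cfg[[k]])),
         character(1))
}

#' Read a run configuration from a flat key=value file
#'
#' Lines of the form `key=value`; blank lines and lines starting with `#`
#' are ignored.  Unknown keys are an error.  Values `auto`, `null`, or an
#' empty string mean the automatic default.
#'
#' @param path Path to the config file.
#' @param base Configuration to override (default [run_config()] defaults).
#' @return A `"run_config"`.
#' @export
read_config <- function(path, base = run_config()) {
  if (!file.exists(path))
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- as.list(unclass(base))
  numeric_keys <- c("w1", "w2", "px", "horizon_percentile", "horizon_cap",
                    "n_rate_nodes", "fit_window", "seed", "verbosity")
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop(sprintf("malformed config line (expected key=value): '%s'", ln),
           call. = FALSE)
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    if (!key %in% names(args))
      stop(sprintf("unknown config key '%s'", key), call. = FALSE)
    if (tolower(val) %in% c("auto", "null", "")) {
      args[key] <- list(NULL)
    } else if (key %in% numeric_keys) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num))
        stop(sprintf("config key '%s': '%s' is not numeric", key, val),
             call. = FALSE)
      args[[key]] <- num
    } else {
      args[[key]] <- val
    }
  }
  do.call(run_config, args)
}

# value_params view of a run_config
config_value_params <- function(cfg) {
  value_params(cfg$w1, cfg$w2, cfg$px)
}
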