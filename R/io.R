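#' Read and write trajectories as CSV
#'
#' The format is a header row `time,<state_names...>` followed by one row
#' per sample. Values are written with full round-trip precision, so
#' `load_timeseries_csv(save_timeseries_csv(x, f))` reproduces `x` exactly.
#'
#' @param traj a [trajectory()].
#' @param path file path.
#' @return `save_timeseries_csv` returns `path` invisibly;
#'   `load_timeseries_csv` returns a [trajectory()].
#' @export
save_timeseries_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  m <- cbind(time = traj$times, traj$values)
  lines <- c(paste(colnames(m), collapse = ","),
             apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname save_timeseries_csv
#' @export
load_timeseries_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("missing 'time' column")
  if (any(!vapply(df, is.numeric, logical(1)))) stop("non-numeric column in time series file")
  vars <- setdiff(names(df), "time")
  trajectory(df$time, as.matrix(df[vars]), vars)
}

#' Export and import a delay library as CSV
#'
#' Flat format for inspection and fixtures: one row per delay vector with
#' columns `row`, `source_time`, the coordinates `v0..vd`, and the stored
#' futures `lead1..leadL` (empty where unavailable).
#'
#' @param lib a [build_delay_library()] object.
#' @param path file path.
#' @return `save_delay_library_csv` returns `path` invisibly;
#'   `load_delay_library_csv` returns a `delay_library` (with the embedding
#'   configuration restored from the file's shape; `kappa` defaults to 1).
#' @export
save_delay_library_csv <- function(lib, path) {
  m <- cbind(row = seq_len(nrow(lib$vectors)), source_time = lib$source_times,
             lib$vectors, lib$futures)
  colnames(m) <- c("row", "source_time", paste0("v", 0:(ncol(lib$vectors) - 1L)),
                   paste0("lead", seq_len(ncol(lib$futures))))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname save_delay_library_csv
#' @param tau time delay of the stored vectors (not recoverable from the
#'   flat file).
#' @export
load_delay_library_csv <- function(path, tau = 1) {
  df <- utils::read.csv(path)
  vcols <- grep("^v[0-9]+$", names(df))
  fcols <- grep("^lead[0-9]+$", names(df))
  cfg <- embedding_config(d = length(vcols) - 1L, tau = tau, kappa = 1)
  structure(list(vectors = as.matrix(df[vcols]),
                 futures = as.matrix(df[fcols]),
                 source_times = df$source_time, cfg = cfg,
                 max_lead = length(fcols),
                 series_length = max(df$source_time)),
            class = "delay_library")
}

#' Load an experiment configuration from a YAML file
#'
#' Flat key/value file mirroring the [experiment_config()] field names;
#' embedding settings are given as a nested block `embedding: {d: 9, tau: 1,
#' kappa: 20}`. Fields not present fall back to the system preset.
#'
#' @param path YAML file path.
#' @return an [experiment_config()].
#' @export
load_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$system) || is.null(y$method))
    stop("config must name at least 'system' and 'method'")
  if (!is.null(y$embedding)) y$embedding <- do.call(embedding_config, y$embedding)
  if (!is.null(y$replace))     # YAML reads bare y/n as booleans
    y$replace <- vapply(y$replace, function(v) {
      if (isTRUE(v)) "y" else if (isFALSE(v)) "n" else as.character(v)
    }, character(1))
  args <- c(list(system = y$system, method = y$method),
            y[setdiff(names(y), c("system", "method"))])
  do.call(experiment_preset, args)
}

#' Write experiment outputs as CSV
#'
#' Writes `estimates.csv` (parameter summaries, if the method estimates
#' parameters) and `srmse.csv` (per-variable, per-lead mean SRMSE and
#' standard error) into a directory.
#'
#' @param result an `experiment_result` from [run_experiment()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
save_experiment_csv <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(result$estimates))
    utils::write.csv(result$estimates, file.path(out_dir, "estimates.csv"),
                     row.names = FALSE)
  if (!is.null(result$srmse)) {
    rows <- do.call(rbind, lapply(names(result$srmse), function(v) {
      s <- result$srmse[[v]]
      data.frame(variable = v, lead = seq_along(s$mean), mean_srmse = s$mean,
                 standard_error = s$se)
    }))
    utils::write.csv(rows, file.path(out_dir, "srmse.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}
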