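# Plain-text serialization: recordings as TSV matrices with a JSON sidecar,
# event and truth tables as TSV, paradigm configuration as YAML, and the
# registration record as JSON. Everything round-trips without value change.

#' Write an EEG recording as a delimited matrix
#'
#' The signal is written as a TSV with one column per channel (header =
#' channel labels) and one row per sample; a JSON sidecar
#' (`<path>.json`) stores the sampling rate and geometry.
#'
#' @param recording An [eeg_recording()].
#' @param path Output TSV path.
#' @export
write_recording_tsv <- function(recording, path) {
  utils::write.table(t(recording$data), path, sep = "\t", row.names = FALSE,
                     col.names = recording$channel_labels, quote = FALSE)
  meta <- list(sampling_rate = recording$sampling_rate,
               channel_labels = recording$channel_labels,
               n_samples = ncol(recording$data))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = I(17)),
             paste0(path, ".json"))
  invisible(path)
}

#' Read an EEG recording written by [write_recording_tsv()]
#'
#' @param path TSV path (the `<path>.json` sidecar must exist).
#' @return An [eeg_recording()].
#' @export
read_recording_tsv <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  eeg_recording(t(m), meta$sampling_rate, meta$channel_labels)
}

#' Write an event table
#'
#' Tab-separated with columns `onset_s`, `node_id`, `kind`,
#' `phase_condition`, `is_target`, `block`.
#'
#' @param events Event data frame.
#' @param path Output path.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an event table written by [write_events_tsv()]
#' @param path TSV path.
#' @return Event data frame.
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
}

#' Write a paradigm configuration as YAML
#' @param cfg A [paradigm_config()].
#' @param path Output path.
#' @export
write_config_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a paradigm configuration from YAML
#' @param path YAML path.
#' @return A [paradigm_config()].
#' @export
read_config_yaml <- function(path) {
  do.call(paradigm_config, yaml::read_yaml(path))
}

#' Write a generated session to a directory
#'
#' Writes `signals.tsv` (+ sidecar), `events.tsv`, one `truth_<name>.tsv`
#' per truth table, and `config.yaml`.
#'
#' @param session A `bci_session`.
#' @param dir Output directory (created if missing).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_recording_tsv(session$recording, file.path(dir, "signals.tsv"))
  write_events_tsv(session$events, file.path(dir, "events.tsv"))
  for (nm in names(session$truth))
    utils::write.table(session$truth[[nm]],
                       file.path(dir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  write_config_yaml(session$cfg, file.path(dir, "config.yaml"))
  meta <- list(kind = session$kind,
               node_ids = vapply(session$nodes, `[[`, integer(1), "node_id"),
               delays = vapply(session$nodes, `[[`, numeric(1),
                               "transmission_delay"))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = I(17)),
             file.path(dir, "session.json"))
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir Session directory.
#' @return A `bci_session`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "session.json"))
  cfg <- read_config_yaml(file.path(dir, "config.yaml"))
  truth_files <- list.files(dir, pattern = "^truth_.*\\.tsv$")
  truth <- stats::setNames(
    lapply(truth_files, function(f)
      utils::read.table(file.path(dir, f), header = TRUE, sep = "\t")),
    sub("^truth_(.*)\\.tsv$", "\\1", truth_files))
  nodes <- lapply(seq_along(meta$node_ids), function(i)
    node_timing(meta$node_ids[i], meta$delays[i]))
  new_session(read_recording_tsv(file.path(dir, "signals.tsv")),
              read_events_tsv(file.path(dir, "events.tsv")),
              truth, cfg, nodes, NULL, meta$kind)
}

#' Serialize a registration record to JSON
#'
#' Stores the phase lags, measured centroids, trained fuzzy parameters,
#' fitness history, predicted centroids, and the spatial filter at full
#' precision; round-trips through [registration_record_from_json()].
#'
#' @param record A `registration_record`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to a file).
#' @export
registration_record_to_json <- function(record, path = NULL) {
  obj <- list(
    lags = record$lags,
    centroids = record$centroids,
    params = jsonlite::fromJSON(it2f_params_to_json(record$fit$params),
                                simplifyVector = FALSE),
    history = record$fit$history,
    train_rmse = record$fit$train_rmse,
    eval_rmse = record$fit$eval_rmse,
    best_fitness = record$fit$best_fitness,
    predicted_tc = as.list(record$predicted_tc),
    cca = list(W_M = record$cca$W_M, W_N = record$cca$W_N,
               rho = record$cca$rho, n_keep = record$cca$n_keep,
               channel_labels = record$cca$channel_labels)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Read a registration record from JSON
#'
#' @param path File path or JSON string from
#'   [registration_record_to_json()].
#' @return A `registration_record` (without the raw training dataset).
#' @export
registration_record_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  params <- it2f_params_from_json(
    jsonlite::toJSON(jsonlite::fromJSON(path, simplifyVector = FALSE)$params,
                     auto_unbox = TRUE, digits = I(17)))
  fit <- structure(list(params = params, history = obj$history,
                        best_fitness = obj$best_fitness,
                        train_rmse = obj$train_rmse,
                        eval_rmse = obj$eval_rmse), class = "it2f_fit")
  cca <- structure(list(W_M = obj$cca$W_M, W_N = obj$cca$W_N,
                        rho = obj$cca$rho,
                        n_keep = as.integer(obj$cca$n_keep),
                        channel_labels = obj$cca$channel_labels),
                   class = "spatial_filter")
  structure(list(
    lags = obj$lags, centroids = obj$centroids, fit = fit,
    predicted_tc = unlist(obj$predicted_tc), cca = cca
  ), class = "registration_record")
}

#' Write an experiment metrics table
#'
#' Tidy TSV with columns subject, epoch_length_ms, calibrated, accuracy,
#' itr (mirroring the reference table layout).
#'
#' @param grid An `experiment_grid` data frame.
#' @param path Output path.
#' @export
write_metrics_tsv <- function(grid, path) {
  utils::write.table(grid, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
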