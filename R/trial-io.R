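#' Write a trial to a directory of plain-text files
#'
#' Writes `forces.csv`, `markers.csv`, `emg.csv`, `belt.csv`,
#' `meta.json`, and (when ground truth is present) `truth.json`.
#'
#' @param trial a `gait_trial`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "gait_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trial$forces, file.path(dir, "forces.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$markers, file.path(dir, "markers.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$emg, file.path(dir, "emg.csv"), row.names = FALSE)
  utils::write.csv(trial$belt, file.path(dir, "belt.csv"),
                   row.names = FALSE)
  jsonlite::write_json(trial$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(trial$truth)) {
    tr <- list(events = trial$truth$events,
               strides = trial$truth$strides,
               activation = trial$truth$activation,
               artifact_strides = trial$truth$artifact_strides)
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(dir)
}

#' Read a trial from a directory written by [write_trial()]
#'
#' @param dir trial directory.
#' @return a `gait_trial` (without generator internals; analyses that
#'   need only the data streams work unchanged).
#' @export
read_trial <- function(dir) {
  trial <- list(
    forces = utils::read.csv(file.path(dir, "forces.csv")),
    markers = utils::read.csv(file.path(dir, "markers.csv")),
    emg = utils::read.csv(file.path(dir, "emg.csv")),
    belt = utils::read.csv(file.path(dir, "belt.csv")),
    meta = jsonlite::read_json(file.path(dir, "meta.json"),
                               simplifyVector = TRUE),
    forces_filtered = FALSE)
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf))
    trial$truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  class(trial) <- "gait_trial"
  trial
}

#' Full offline analysis of a walking trial
#'
#' Runs the complete pipeline on a trial: force filtering, event
#' detection and pairing, per-stride propulsion metrics, and EMG
#' activations, merged into one per-stride table (`strides.csv` layout).
#'
#' @param trial a `gait_trial`.
#' @param baseline_window see [emg_activations()].
#' @param remove_outliers see [emg_activations()].
#' @return list with `events`, `metrics` (per-stride kinetics and
#'   kinematics), `activations` (per stride x muscle), and `strides`:
#'   the metrics table with one normalized-activation column per muscle
#'   and an `outlier` flag (any muscle flagged).
#' @export
analyze_trial <- function(trial, baseline_window = NULL,
                          remove_outliers = TRUE) {
  trial <- filter_forces(trial)
  events <- detect_gait_events(trial)
  metrics <- stride_metrics(trial, events)
  act <- emg_activations(trial, events, baseline_window = baseline_window,
                         remove_outliers = remove_outliers)
  wide <- metrics
  wide$outlier <- FALSE
  for (mus in unique(act$muscle)) {
    col <- paste0("act_", mus)
    wide[[col]] <- NA_real_
    for (lg in unique(wide$leg)) {
      a <- act[act$leg == lg & act$muscle == mus, ]
      wi <- which(wide$leg == lg)
      idx <- match(wide$stride[wi], a$stride)
      wide[[col]][wi] <- a$normalized[idx]
      wide$outlier[wi] <- wide$outlier[wi] | (a$outlier[idx] %in% TRUE)
    }
  }
  list(events = events, metrics = metrics, activations = act,
       strides = wide)
}
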