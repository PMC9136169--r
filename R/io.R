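# CSV interchange for trials, manifests and feature tables ---------------

#' Write a cohort as per-trial CSV files plus a manifest
#'
#' Each trial becomes one CSV with columns `t_s, lx, ly, lz, rx, ry, rz`
#' (time in seconds, acceleration in g); `manifest.csv` lists
#' `participant_id, trial_id, label, fs, file`. Ground-truth heel-strike
#' indices are simulator-internal and are not written.
#'
#' @param cohort Cohort tibble from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    f <- sprintf("%s_%s.csv", cohort$participant_id[[i]], cohort$trial_id[[i]])
    readr::write_csv(cohort$signal[[i]], file.path(dir, f))
    files[i] <- f
  }
  manifest <- tibble::tibble(
    participant_id = cohort$participant_id,
    trial_id = cohort$trial_id,
    label = cohort$label,
    fs = cohort$fs,
    file = files
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a cohort back from a manifest
#'
#' Rebuilds a cohort tibble from a `manifest.csv` written by
#' [write_cohort()] (or prepared by hand for real recordings). Ground-truth
#' heel-strike columns are empty: for measured data they are unknown and the
#' pipeline detects strikes from the signal.
#'
#' @param manifest_path Path to the manifest CSV; trial files are resolved
#'   relative to its directory.
#' @return A cohort tibble in the shape of [simulate_cohort()] output.
#' @export
read_cohort <- function(manifest_path) {
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
  base <- dirname(manifest_path)
  needed <- c("participant_id", "trial_id", "label", "fs", "file")
  missing <- setdiff(needed, names(manifest))
  if (length(missing)) {
    abort(paste0("manifest lacks column(s): ", paste(missing, collapse = ", ")))
  }
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    sig <- readr::read_csv(file.path(base, manifest$file[[i]]),
                           show_col_types = FALSE)
    tibble::tibble(
      participant_id = manifest$participant_id[[i]],
      trial_id = as.character(manifest$trial_id[[i]]),
      label = as.integer(manifest$label[[i]]),
      group = ifelse(manifest$label[[i]] == 1L, "non_faller", "recurrent_faller"),
      fs = manifest$fs[[i]],
      signal = list(sig),
      hs_left = list(integer(0)),
      hs_right = list(integer(0))
    )
  })
  dplyr::bind_rows(rows)
}

#' Write and read the gait-pattern feature table
#'
#' The feature CSV holds one row per (trial, source) with the 8 features,
#' the class label and identifiers, and round-trips losslessly at full
#' double precision.
#'
#' @param features Feature tibble from [extract_gait_features()].
#' @param path CSV path.
#' @return `write_gait_features()` returns `path` invisibly;
#'   `read_gait_features()` returns the feature tibble.
#' @export
write_gait_features <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_gait_features
#' @export
read_gait_features <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    participant_id = readr::col_character(),
                    trial_id = readr::col_character(),
                    source = readr::col_character(),
                    gait_label = readr::col_integer(),
                    .default = readr::col_double()
                  ))
}
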