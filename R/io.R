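#' Write / read a trial table as BIDS-events-style TSV
#'
#' Tab-separated with \code{onset} and \code{duration} first, as in BIDS
#' events files, plus the task columns.
#'
#' @param table A \code{trial_table}.
#' @param path Output .tsv path.
#' @param duration_s Event duration written to the \code{duration} column.
#' @return \code{path}, invisibly.
#' @export
write_trial_table <- function(table, path, duration_s = 3) {
  df <- data.frame(onset = table$onset_s, duration = duration_s,
                   trial_id = table$trial_id, stimulus = table$stimulus,
                   phase = table$phase, block = table$block,
                   modality = table$modality, confidence = table$confidence,
                   correct = as.integer(table$correct),
                   remembered = as.integer(table$remembered))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- utils::read.delim(path)
  out <- data.frame(trial_id = df$trial_id, stimulus = df$stimulus,
                    phase = df$phase, block = df$block,
                    modality = df$modality, confidence = df$confidence,
                    correct = df$correct == 1, remembered = df$remembered == 1,
                    onset_s = df$onset)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Write per-trial information as TSV
#'
#' Keyed by \code{trial_id} so it merges cleanly with trial power tables.
#'
#' @param info A \code{trial_information} data.frame.
#' @param path Output .tsv path.
#' @return \code{path}, invisibly.
#' @export
write_trial_information <- function(info, path) {
  utils::write.table(info, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export an information map as NIfTI on the searchlight grid
#'
#' Writes the per-centre Fisher z values into a volume with the searchlight
#' map's grid and spacing (default 3 x 3 x 4 mm affine). Requires the
#' RNifti package.
#'
#' @param z Named vector from \code{\link{searchlight_information_map}}.
#' @param searchlights The \code{searchlight_map} the values live on.
#' @param path Output .nii path.
#' @return \code{path}, invisibly.
#' @export
write_info_map_nifti <- function(z, searchlights, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required for NIfTI export", call. = FALSE)
  }
  vol <- array(NA_real_, dim(searchlights$mask))
  centre_grid <- which(searchlights$mask)[searchlights$centres]
  vol[centre_grid] <- z
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- searchlights$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export a searchlight map as JSON
#'
#' One object per centre voxel mapping to its member voxel indices.
#' Requires the jsonlite package.
#'
#' @param searchlights A \code{searchlight_map}.
#' @param path Output .json path.
#' @return \code{path}, invisibly.
#' @export
write_searchlights_json <- function(searchlights, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required for JSON export", call. = FALSE)
  }
  obj <- stats::setNames(searchlights$members,
                         as.character(searchlights$centres))
  jsonlite::write_json(obj, path)
  invisible(path)
}
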