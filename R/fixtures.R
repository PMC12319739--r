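#' Write a fixture bundle to disk
#'
#' Serializes a schedule (TSV), timeline/recognition/association responses
#' (TSV), the generating parameters (JSON sidecar), and optionally a
#' simulated BOLD volume with its mask (NIfTI-1) and BIDS-style events
#' table, for regression tests and external tools.
#'
#' @param path Output directory (created if needed).
#' @param schedule A `tm_schedule`.
#' @param responses Optional `tm_responses` or list of them.
#' @param bold Optional `tm_bold`.
#' @return Invisibly, the vector of files written.
#' @export
write_fixture_bundle <- function(path, schedule, responses = NULL, bold = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  wt <- function(df, name) {
    f <- file.path(path, name)
    utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
    written <<- c(written, f)
  }
  wt(schedule$episodes, "episodes.tsv")
  wt(schedule$objects, "objects.tsv")
  wt(schedule$events, "events.tsv")
  params <- list(design = unclass(schedule$design))
  if (!is.null(responses)) {
    if (inherits(responses, "tm_responses")) responses <- list(responses)
    wt(do.call(rbind, lapply(responses, `[[`, "timeline1")), "timeline1.tsv")
    wt(do.call(rbind, lapply(responses, `[[`, "timeline2")), "timeline2.tsv")
    wt(do.call(rbind, lapply(responses, `[[`, "association")), "association.tsv")
    rec <- do.call(rbind, lapply(responses, function(r)
      data.frame(participant = r$participant,
                 object_id = r$recognition$selected_ids)))
    wt(rec, "recognition_selected.tsv")
    wt(do.call(rbind, lapply(responses, `[[`, "meta")), "participants.tsv")
    params$participants <- lapply(responses, function(r) unclass(r$model))
  }
  if (!is.null(bold)) {
    f <- file.path(path, "bold.nii.gz")
    vol <- bold_to_volume(bold)
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = c(rep(bold$spec$voxel_size, 3),
                                                       bold$spec$tr)), f)
    written <- c(written, f)
    fm <- file.path(path, "mask.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(array(as.numeric(bold$mask),
                                             dim(bold$mask))), fm)
    written <- c(written, fm)
    params$bold_spec <- unclass(bold$spec)
  }
  fj <- file.path(path, "parameters.json")
  jsonlite::write_json(params, fj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, fj)
  invisible(written)
}

#' Read a fixture bundle
#'
#' Reads back the tables written by [write_fixture_bundle()] and validates
#' the schedule schema; a truncated or column-mangled file is an error.
#'
#' @param path Bundle directory.
#' @return List with `episodes`, `objects`, `events`, `params`, and (when
#'   present) `timeline1`, `timeline2`, `association`,
#'   `recognition_selected`, `participants`, `bold`, `mask`.
#' @export
read_fixture_bundle <- function(path) {
  rd <- function(name, required_cols) {
    f <- file.path(path, name)
    if (!file.exists(f)) return(NULL)
    df <- utils::read.delim(f, sep = "\t", stringsAsFactors = FALSE)
    missing <- setdiff(required_cols, names(df))
    if (length(missing) > 0)
      stop("fixture file ", name, " is missing columns: ",
           paste(missing, collapse = ", "))
    if (anyNA(df[, required_cols]))
      stop("fixture file ", name, " contains missing values in required columns")
    df
  }
  out <- list(
    episodes = rd("episodes.tsv", c("run", "episode", "green_onset", "red_onset")),
    objects = rd("objects.tsv", c("run", "episode", "object_index", "object_id", "onset")),
    events = rd("events.tsv", c("run", "episode", "onset", "duration", "trial_type")),
    timeline1 = rd("timeline1.tsv", c("participant", "run", "episode",
                                      "object_id", "placed_time")),
    timeline2 = rd("timeline2.tsv", c("participant", "run", "episode", "placed_time")),
    association = rd("association.tsv", c("participant", "run", "episode", "correct")),
    recognition_selected = rd("recognition_selected.tsv", c("participant", "object_id")),
    participants = rd("participants.tsv", "participant"))
  if (is.null(out$episodes)) stop("not a fixture bundle: episodes.tsv missing")
  fj <- file.path(path, "parameters.json")
  if (file.exists(fj)) out$params <- jsonlite::read_json(fj, simplifyVector = TRUE)
  fb <- file.path(path, "bold.nii.gz")
  if (file.exists(fb)) {
    out$bold <- RNifti::readNifti(fb)
    out$mask <- RNifti::readNifti(file.path(path, "mask.nii.gz"))
  }
  out
}
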