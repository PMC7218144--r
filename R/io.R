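#' Read a multichannel ECoG recording
#'
#' Reads a recording file plus its JSON annotation sidecar into a list of
#' [ecog_recording()] objects, one per channel.  Two on-disk formats are
#' supported:
#'
#' * `csv` — one column per channel, header row = channel ids; the sampling
#'   rate comes from the sidecar.  Samples round-trip bit-comparably.
#' * `edf` — European Data Format (16-bit); the sampling rate comes from the
#'   EDF header and samples round-trip within the format's quantisation step.
#'
#' The sidecar (`<path>.json` by default) carries the sampling rate (csv), the
#' block annotations and optional per-channel ground-truth labels:
#' `{"fs": 1200, "blocks": [{"condition": "active", "story_id": 1,
#' "start_sample": 0, "end_sample": 36000}, ...], "labels": {"ch01": "PRC"}}`.
#' Block annotations use 0-based, half-open sample intervals and are shared by
#' all channels (the task paradigm is common to the grid).
#'
#' @param path Path to the recording file.
#' @param format `"csv"` or `"edf"`; the default guesses from the extension.
#' @param sidecar Path to the JSON sidecar; `NULL` means `<path>.json`, and a
#'   missing sidecar yields recordings with empty annotations.
#' @return List of [ecog_recording()] objects, in file channel order.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"), sidecar = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("Cannot read recording: file '%s' does not exist.", path),
          class = "ecogmapr_io_error")
  }
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", edf = "edf",
                     abort(sprintf("Cannot guess format of '%s'; pass `format`.", path),
                           class = "ecogmapr_io_error"))
  }
  if (is.null(sidecar)) sidecar <- paste0(path, ".json")
  side <- if (file.exists(sidecar)) read_sidecar(sidecar) else NULL

  if (format == "csv") {
    # base strtod parsing restores readr's shortest-round-trip doubles exactly
    dat <- utils::read.csv(path, check.names = FALSE, colClasses = "numeric")
    if (is.null(side) || is.null(side$fs)) {
      abort(sprintf("CSV recording '%s' needs a sidecar with an `fs` entry.", path),
            class = "ecogmapr_format_error")
    }
    fs <- side$fs
    channels <- names(dat)
    signals <- lapply(channels, function(ch) dat[[ch]])
    names(signals) <- channels
  } else {
    edf <- read_edf(path)
    fs <- edf$fs
    channels <- names(edf$signals)
    signals <- edf$signals
  }
  if (!is.numeric(fs) || length(fs) != 1L || is.na(fs) || fs <= 0) {
    abort(sprintf("Recording '%s': sampling rate missing or non-positive.", path),
          class = "ecogmapr_format_error")
  }

  ann <- if (!is.null(side)) side$blocks else empty_annotations()
  labels <- if (!is.null(side)) side$labels else NULL
  lapply(channels, function(ch) {
    lab <- if (!is.null(labels) && ch %in% names(labels)) labels[[ch]] else NA_character_
    ecog_recording(ch, signals[[ch]], fs, annotations = ann, truth_label = lab)
  })
}

#' Write a multichannel ECoG recording
#'
#' Inverse of [read_recording()]: writes all channels to one file plus the JSON
#' annotation sidecar.  All recordings must share the same sampling rate and
#' (for a rectangular file) the same length; annotations are taken from the
#' first channel (the paradigm is grid-wide).
#'
#' @param recordings List of [ecog_recording()] objects.
#' @param path Output file path.
#' @param format `"csv"` or `"edf"` (default guesses from extension).
#' @param sidecar Sidecar path; `NULL` means `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(recordings, path, format = c("auto", "csv", "edf"),
                            sidecar = NULL) {
  format <- match.arg(format)
  if (is_ecog_recording(recordings)) recordings <- list(recordings)
  stopifnot(length(recordings) >= 1)
  if (!all(vapply(recordings, is_ecog_recording, logical(1)))) {
    abort("`recordings` must be a list of ecog_recording objects.",
          class = "ecogmapr_validation_error")
  }
  fs_all <- vapply(recordings, function(r) r$fs, numeric(1))
  if (length(unique(fs_all)) != 1L) {
    abort("All recordings must share the same sampling rate.",
          class = "ecogmapr_validation_error")
  }
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", edf = "edf",
                     abort(sprintf("Cannot guess format of '%s'; pass `format`.", path),
                           class = "ecogmapr_io_error"))
  }
  if (is.null(sidecar)) sidecar <- paste0(path, ".json")

  ids <- vapply(recordings, function(r) r$channel_id, character(1))
  if (anyDuplicated(ids)) {
    abort("Duplicate channel ids in cohort.", class = "ecogmapr_validation_error")
  }

  if (format == "csv") {
    lens <- vapply(recordings, function(r) length(r$samples), integer(1))
    if (length(unique(lens)) != 1L) {
      abort("CSV output needs equal-length channels.", class = "ecogmapr_validation_error")
    }
    dat <- tibble::as_tibble(setNames(lapply(recordings, function(r) r$samples), ids))
    readr::write_csv(dat, path, progress = FALSE)
  } else {
    write_edf(recordings, path)
  }
  write_sidecar(recordings, sidecar)
  invisible(path)
}

read_sidecar <- function(path) {
  side <- jsonlite::read_json(path, simplifyVector = FALSE)
  blocks <- if (!is.null(side$blocks)) {
    tibble::tibble(
      condition = vapply(side$blocks, function(b) as.character(b$condition), character(1)),
      story_id = vapply(side$blocks, function(b)
        if (is.null(b$story_id)) NA_integer_ else as.integer(b$story_id), integer(1)),
      start_sample = vapply(side$blocks, function(b) as.integer(b$start_sample), integer(1)),
      end_sample = vapply(side$blocks, function(b) as.integer(b$end_sample), integer(1))
    )
  } else {
    empty_annotations()
  }
  labels <- if (!is.null(side$labels)) {
    vapply(side$labels, as.character, character(1))
  } else NULL
  list(fs = if (is.null(side$fs)) NULL else as.double(side$fs),
       blocks = blocks, labels = labels)
}

write_sidecar <- function(recordings, path) {
  ann <- recordings[[1]]$annotations
  blocks <- lapply(seq_len(nrow(ann)), function(i) {
    b <- list(condition = ann$condition[i],
              start_sample = ann$start_sample[i],
              end_sample = ann$end_sample[i])
    if (!is.na(ann$story_id[i])) b$story_id <- ann$story_id[i]
    b
  })
  labs <- vapply(recordings, function(r) r$truth_label, character(1))
  names(labs) <- vapply(recordings, function(r) r$channel_id, character(1))
  labs <- labs[!is.na(labs)]
  side <- list(fs = recordings[[1]]$fs, blocks = blocks)
  if (length(labs) > 0) side$labels <- as.list(labs)
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
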