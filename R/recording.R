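#' Annotated ECoG recording
#'
#' The canonical in-memory representation of one channel's continuous signal
#' together with its task annotations.  Amplitudes are kept in the units they
#' arrived in (nominally microvolts, arbitrary reference) and are never
#' rescaled implicitly.  Sample indexing is 0-based and block intervals are
#' half-open `[start_sample, end_sample)`.
#'
#' @param channel_id Single string naming the electrode/channel.
#' @param samples Numeric vector of amplitudes.
#' @param fs Sampling rate in Hz (positive scalar; nominally 1200).
#' @param annotations Tibble/data frame of block annotations with columns
#'   `condition` ("control"/"active"), `story_id` (integer, `NA` for control
#'   blocks), `start_sample`, `end_sample` (0-based, half-open).  May have
#'   zero rows.
#' @param truth_label Optional ground-truth channel label, `"PRC"` or `"NRC"`
#'   (positive/negative response channel, per stimulation mapping), else `NA`.
#' @param units Amplitude unit string carried as metadata (default `"uV"`).
#'
#' @return An object of class `ecog_recording`.
#' @export
ecog_recording <- function(channel_id, samples, fs,
                           annotations = empty_annotations(),
                           truth_label = NA_character_,
                           units = "uV") {
  if (!is.character(channel_id) || length(channel_id) != 1L || is.na(channel_id)) {
    abort("`channel_id` must be a single non-missing string.", class = "ecogmapr_validation_error")
  }
  if (!is.numeric(fs) || length(fs) != 1L || is.na(fs) || fs <= 0) {
    abort("`fs` must be a single positive number.", class = "ecogmapr_format_error")
  }
  samples <- as.double(samples)
  if (anyNA(samples)) {
    abort("`samples` must not contain missing values.", class = "ecogmapr_validation_error")
  }
  annotations <- as_annotations(annotations)
  validate_annotations(annotations, n_samples = length(samples), channel_id = channel_id)
  truth_label <- as.character(truth_label)
  if (!is.na(truth_label) && !truth_label %in% c("PRC", "NRC")) {
    abort("`truth_label` must be \"PRC\", \"NRC\" or NA.", class = "ecogmapr_validation_error")
  }
  structure(
    list(
      channel_id = channel_id,
      samples = samples,
      fs = as.double(fs),
      annotations = annotations,
      truth_label = truth_label,
      units = units
    ),
    class = "ecog_recording"
  )
}

empty_annotations <- function() {
  tibble::tibble(
    condition = character(),
    story_id = integer(),
    start_sample = integer(),
    end_sample = integer()
  )
}

as_annotations <- function(x) {
  x <- tibble::as_tibble(x)
  needed <- c("condition", "start_sample", "end_sample")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Annotations are missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."),
          class = "ecogmapr_validation_error")
  }
  if (!"story_id" %in% names(x)) x$story_id <- NA_integer_
  tibble::tibble(
    condition = as.character(x$condition),
    story_id = as.integer(x$story_id),
    start_sample = as.integer(x$start_sample),
    end_sample = as.integer(x$end_sample)
  )
}

validate_annotations <- function(ann, n_samples, channel_id = "?") {
  if (nrow(ann) == 0) return(invisible(ann))
  if (!all(ann$condition %in% c("control", "active"))) {
    abort("Annotation `condition` must be \"control\" or \"active\".",
          class = "ecogmapr_validation_error")
  }
  if (any(ann$start_sample < 0) || any(ann$end_sample > n_samples) ||
      any(ann$end_sample <= ann$start_sample)) {
    abort(sprintf("Channel %s: annotations must satisfy 0 <= start < end <= n_samples.",
                  channel_id),
          class = "ecogmapr_validation_error")
  }
  if (is.unsorted(ann$start_sample)) {
    abort(sprintf("Channel %s: annotations must be sorted by start_sample.", channel_id),
          class = "ecogmapr_validation_error")
  }
  if (nrow(ann) > 1) {
    overlap <- which(ann$start_sample[-1] < ann$end_sample[-nrow(ann)])
    if (length(overlap) > 0) {
      i <- overlap[1]
      abort(sprintf("Channel %s: annotations %d and %d overlap ([%d,%d) vs [%d,%d)).",
                    channel_id, i, i + 1L,
                    ann$start_sample[i], ann$end_sample[i],
                    ann$start_sample[i + 1L], ann$end_sample[i + 1L]),
            class = "ecogmapr_validation_error")
    }
  }
  active_missing <- ann$condition == "active" & is.na(ann$story_id)
  if (any(active_missing)) {
    warn("Active block(s) without a story_id.")
  }
  invisible(ann)
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("<ecog_recording> channel %s: %d samples @ %g Hz (%.1f s), %d block(s), label %s\n",
              x$channel_id, length(x$samples), x$fs, length(x$samples) / x$fs,
              nrow(x$annotations),
              ifelse(is.na(x$truth_label), "unknown", x$truth_label)))
  invisible(x)
}

#' @export
format.ecog_recording <- function(x, ...) {
  sprintf("<ecog_recording %s: %d samples @ %g Hz>", x$channel_id,
          length(x$samples), x$fs)
}

is_ecog_recording <- function(x) inherits(x, "ecog_recording")

#' Cohort label manifest
#'
#' Summarise a list of recordings as a tibble of channel ids and truth labels,
#' the tabular handle the evaluation stage works with.
#'
#' @param recordings List of [ecog_recording()] objects.
#' @return Tibble with columns `channel_id`, `label`.
#' @export
cohort_manifest <- function(recordings) {
  stopifnot(all(vapply(recordings, is_ecog_recording, logical(1))))
  tibble::tibble(
    channel_id = vapply(recordings, function(r) r$channel_id, character(1)),
    label = vapply(recordings, function(r) r$truth_label, character(1))
  )
}
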