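#' Trim a recording to the annotated task interval
#'
#' Discards spontaneous activity before the first task block and trailing
#' signal after the last one, re-indexing the annotations to the trimmed
#' origin.  Idempotent: trimming a trimmed recording is a no-op.
#'
#' @param rec An [ecog_recording()] with at least one annotation.
#' @return The trimmed [ecog_recording()].
#' @export
trim_to_task <- function(rec) {
  stopifnot(is_ecog_recording(rec))
  ann <- rec$annotations
  if (nrow(ann) == 0) {
    abort(sprintf("Channel %s: cannot trim a recording with no annotations.",
                  rec$channel_id),
          class = "ecogmapr_validation_error")
  }
  first <- ann$start_sample[1]
  last <- ann$end_sample[nrow(ann)]
  rec$samples <- rec$samples[(first + 1L):last]
  rec$annotations <- dplyr::mutate(ann,
                                   start_sample = .data$start_sample - first,
                                   end_sample = .data$end_sample - first)
  rec
}

#' Cut a trimmed recording into uniform task blocks
#'
#' One slice per annotation; by default every block must have the same length
#' (`round(block_duration_s * fs)` samples), mirroring the uniform alternating
#' 30 s control/active paradigm.
#'
#' @param rec A trimmed [ecog_recording()].
#' @param block_duration_s Expected block duration in seconds (default 30).
#'   Set to `NULL` to accept whatever (uniform) length the annotations define.
#' @return An `ecog_blockset`: a tibble with one row per block and columns
#'   `block_idx`, `condition`, `story_id`, `start_sample`, `end_sample` and a
#'   list-column `samples`; attributes `channel_id`, `fs`, `truth_label`.
#' @export
extract_blocks <- function(rec, block_duration_s = 30) {
  stopifnot(is_ecog_recording(rec))
  ann <- rec$annotations
  if (nrow(ann) == 0) {
    abort("Cannot extract blocks without annotations.",
          class = "ecogmapr_validation_error")
  }
  lens <- ann$end_sample - ann$start_sample
  if (!is.null(block_duration_s)) {
    expected <- as.integer(round(block_duration_s * rec$fs))
    bad <- which(lens != expected)
    if (length(bad) > 0) {
      abort(sprintf("Channel %s: block %d has %d samples, expected %d.",
                    rec$channel_id, bad[1], lens[bad[1]], expected),
            class = "ecogmapr_validation_error")
    }
  } else if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1])[1]
    abort(sprintf("Channel %s: ragged block lengths (block %d).",
                  rec$channel_id, bad),
          class = "ecogmapr_validation_error")
  }
  slices <- purrr::map2(ann$start_sample, ann$end_sample,
                        function(s, e) rec$samples[(s + 1L):e])
  out <- tibble::tibble(
    block_idx = seq_len(nrow(ann)),
    condition = ann$condition,
    story_id = ann$story_id,
    start_sample = ann$start_sample,
    end_sample = ann$end_sample,
    samples = slices
  )
  structure(out,
            channel_id = rec$channel_id, fs = rec$fs,
            truth_label = rec$truth_label,
            class = c("ecog_blockset", class(out)))
}

#' Overlapping sliding windows over one block
#'
#' Slices a block into sub-block windows of `width` samples every `stride`
#' samples.  Windows never extend past the block end (no padding), so the
#' window count is `floor((L - width) / stride) + 1`.
#'
#' @param block Numeric vector, one block's samples.
#' @param width Window width in samples (default 600, i.e. 0.5 s at 1200 Hz).
#' @param stride Hop between window starts in samples (default 100).
#' @return A `window_set`: list with `windows` (a `width x n` matrix, one
#'   window per column), `start_indices` (0-based), `width`, `stride`.
#' @export
sliding_windows <- function(block, width = 600, stride = 100) {
  block <- as.double(block)
  L <- length(block)
  if (!is.numeric(width) || width < 1 || width != round(width) ||
      !is.numeric(stride) || stride < 1 || stride != round(stride)) {
    abort("`width` and `stride` must be positive integers.",
          class = "ecogmapr_validation_error")
  }
  if (width > L) {
    abort(sprintf("Window width %d exceeds block length %d.", width, L),
          class = "ecogmapr_validation_error")
  }
  n <- (L - width) %/% stride + 1L
  starts <- (seq_len(n) - 1L) * stride
  idx <- outer(seq_len(width), starts, `+`)
  structure(
    list(windows = matrix(block[idx], nrow = width, ncol = n),
         start_indices = as.integer(starts),
         width = as.integer(width), stride = as.integer(stride)),
    class = "window_set"
  )
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of width %d, stride %d (last start %d)\n",
              ncol(x$windows), x$width, x$stride,
              tail(x$start_indices, 1)))
  invisible(x)
}

#' Default 10-block alternating task annotations
#'
#' Builds the standard story-listening paradigm annotation table: alternating
#' control/active blocks, control first, active blocks carrying story ids
#' 1..n_active.
#'
#' @param fs Sampling rate in Hz.
#' @param block_duration_s Block duration in seconds (default 30).
#' @param n_active Number of active (story) blocks, default 5.
#' @param n_control Number of control (noise) blocks, default 5.
#' @param offset_samples 0-based start of the first block (default 0).
#' @return Annotation tibble as in [ecog_recording()].
#' @export
task_annotations <- function(fs, block_duration_s = 30, n_active = 5,
                             n_control = 5, offset_samples = 0) {
  stopifnot(n_active == n_control)  # alternation requires matched counts
  len <- as.integer(round(block_duration_s * fs))
  n <- n_active + n_control
  starts <- offset_samples + (seq_len(n) - 1L) * len
  story <- rep(NA_integer_, n)
  story[seq(2L, n, by = 2L)] <- seq_len(n_active)
  tibble::tibble(
    condition = rep(c("control", "active"), n_active),
    story_id = story,
    start_sample = as.integer(starts),
    end_sample = as.integer(starts + len)
  )
}
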