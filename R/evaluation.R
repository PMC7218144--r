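#' Balance classes by undersampling negative channels
#'
#' Keeps every positive channel and draws an equal-sized uniform subsample of
#' negative channels without replacement (the negatives outnumber positives
#' roughly 3:1 in this setting).
#'
#' @param channels Tibble with columns `channel_id`, `label` (PRC/NRC).
#' @param seed Integer seed for the subsample.
#' @return Balanced tibble (same columns), PRCs first.
#' @export
balance_classes <- function(channels, seed = 1) {
  channels <- tibble::as_tibble(channels)
  prc <- dplyr::filter(channels, .data$label == "PRC")
  nrc <- dplyr::filter(channels, .data$label == "NRC")
  if (nrow(prc) == 0) {
    abort("No positive-response channels to balance against.",
          class = "ecogmapr_validation_error")
  }
  if (nrow(nrc) < nrow(prc)) {
    warn(sprintf("Only %d NRC for %d PRC; keeping all NRC.", nrow(nrc), nrow(prc)))
    return(dplyr::bind_rows(prc, nrc))
  }
  keep <- with_rng_seed(seed, sample.int(nrow(nrc), nrow(prc)))
  dplyr::bind_rows(prc, nrc[sort(keep), ])
}

#' Channel-grouped shuffle-split cross-validation plan
#'
#' Each repeat independently samples a stratified test set of whole channels;
#' all of a channel's blocks travel with it, so no channel is ever on both
#' sides of a split.
#'
#' @param channels Tibble with `channel_id`, `label`.
#' @param n_repeats Number of shuffle-split repeats (default 30).
#' @param test_fraction Fraction of each class held out (default 0.2); at
#'   least one channel per class is always held out.
#' @param seed Integer seed.
#' @return A `cv_plan`: tibble with `repeat_idx` and list-columns `train`,
#'   `test` of channel ids.
#' @export
grouped_shuffle_split <- function(channels, n_repeats = 30, test_fraction = 0.2,
                                  seed = 1) {
  channels <- tibble::as_tibble(channels)
  stopifnot(test_fraction > 0, test_fraction < 1)
  by_class <- split(channels$channel_id, channels$label)
  if (length(by_class) < 2 || any(lengths(by_class) < 2)) {
    abort("Need at least 2 channels per class for a grouped split.",
          class = "ecogmapr_validation_error")
  }
  n_test <- lapply(by_class, function(ids) max(1L, round(test_fraction * length(ids))))
  if (any(unlist(n_test) >= lengths(by_class))) {
    abort("`test_fraction` would leave a class empty in training.",
          class = "ecogmapr_validation_error")
  }
  folds <- with_rng_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      test <- unlist(lapply(names(by_class), function(cl) {
        sample(by_class[[cl]], n_test[[cl]])
      }), use.names = FALSE)
      list(train = setdiff(channels$channel_id, test), test = test)
    })
  })
  out <- tibble::tibble(
    repeat_idx = seq_len(n_repeats),
    train = lapply(folds, `[[`, "train"),
    test = lapply(folds, `[[`, "test")
  )
  structure(out, seed = seed, test_fraction = test_fraction,
            class = c("cv_plan", class(out)))
}

#' Majority vote over sub-block labels
#'
#' A channel is labelled PRC when strictly more than 50% of its sub-blocks
#' respond positive, NRC when strictly fewer, and gets no label (abstain) on
#' an exact tie.
#'
#' @param subblock_labels Character vector of `"positive"`/`"negative"`.
#' @return `"PRC"`, `"NRC"` or `"abstain"`.
#' @export
majority_vote <- function(subblock_labels) {
  if (length(subblock_labels) == 0) {
    abort("Cannot vote over an empty label list.",
          class = "ecogmapr_validation_error")
  }
  if (!all(subblock_labels %in% c("positive", "negative"))) {
    abort("Sub-block labels must be \"positive\" or \"negative\".",
          class = "ecogmapr_validation_error")
  }
  frac <- mean(subblock_labels == "positive")
  if (frac > 0.5) "PRC" else if (frac < 0.5) "NRC" else "abstain"
}

#' Channel-level classification metrics
#'
#' Sensitivity = TP/(TP+FN) over true PRCs, specificity = TN/(TN+FP) over
#' true NRCs, accuracy = channel-level correct fraction, block accuracy =
#' sub-block-level correct fraction; all in percent, averaged (mean +/- sd)
#' across repeats.  Abstaining channels are excluded from the denominators
#' and reported separately.
#'
#' @param predictions Tibble with one row per (repeat, channel):
#'   `repeat_idx`, `channel_id`, `voted_label`, and optionally `n_subblocks`,
#'   `n_subblocks_correct` for block accuracy.  A `truth` column may be
#'   included instead of passing `truth`.
#' @param truth Optional tibble `channel_id`, `label` with ground truth.
#' @return A `metric_report`.
#' @export
compute_metrics <- function(predictions, truth = NULL) {
  predictions <- tibble::as_tibble(predictions)
  if (!"repeat_idx" %in% names(predictions)) predictions$repeat_idx <- 1L
  if (!"truth" %in% names(predictions)) {
    if (is.null(truth)) {
      abort("Supply ground truth (column `truth` or argument `truth`).",
            class = "ecogmapr_validation_error")
    }
    truth <- tibble::as_tibble(truth)
    miss <- setdiff(predictions$channel_id, truth$channel_id)
    if (length(miss) > 0) {
      abort(sprintf("No truth label for channel(s): %s.",
                    paste(head(miss, 5), collapse = ", ")),
            class = "ecogmapr_validation_error")
    }
    predictions <- dplyr::left_join(
      predictions, dplyr::rename(truth, truth = "label"), by = "channel_id")
  }
  has_blocks <- all(c("n_subblocks", "n_subblocks_correct") %in% names(predictions))
  per_repeat <- predictions |>
    dplyr::group_by(.data$repeat_idx) |>
    dplyr::summarise(
      tp = sum(.data$voted_label == "PRC" & .data$truth == "PRC"),
      fn = sum(.data$voted_label == "NRC" & .data$truth == "PRC"),
      tn = sum(.data$voted_label == "NRC" & .data$truth == "NRC"),
      fp = sum(.data$voted_label == "PRC" & .data$truth == "NRC"),
      abstained = sum(.data$voted_label == "abstain"),
      block_accuracy = if (has_blocks) {
        100 * sum(.data$n_subblocks_correct) / sum(.data$n_subblocks)
      } else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(
      sensitivity = 100 * .data$tp / (.data$tp + .data$fn),
      specificity = 100 * .data$tn / (.data$tn + .data$fp),
      accuracy = 100 * (.data$tp + .data$tn) /
        (.data$tp + .data$tn + .data$fp + .data$fn))
  summary <- per_repeat |>
    dplyr::summarise(dplyr::across(
      c("block_accuracy", "sensitivity", "specificity", "accuracy"),
      list(mean = ~mean(.x, na.rm = TRUE), sd = ~sd(.x, na.rm = TRUE))))
  structure(list(per_repeat = per_repeat, summary = summary,
                 n_abstained = sum(per_repeat$abstained),
                 predictions = predictions),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  s <- x$summary
  cat("<metric_report>", nrow(x$per_repeat), "repeat(s)\n")
  cat(sprintf("  accuracy     %6.2f%% +/- %.2f\n", s$accuracy_mean, s$accuracy_sd))
  cat(sprintf("  sensitivity  %6.2f%% +/- %.2f\n", s$sensitivity_mean, s$sensitivity_sd))
  cat(sprintf("  specificity  %6.2f%% +/- %.2f\n", s$specificity_mean, s$specificity_sd))
  if (!is.na(s$block_accuracy_mean)) {
    cat(sprintf("  block acc.   %6.2f%% +/- %.2f\n",
                s$block_accuracy_mean, s$block_accuracy_sd))
  }
  if (x$n_abstained > 0) cat("  abstained:", x$n_abstained, "channel-repeats\n")
  invisible(x)
}

#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) x$per_repeat

#' @method glance metric_report
#' @export
glance.metric_report <- function(x, ...) x$summary

#' @method autoplot metric_report
#' @export
autoplot.metric_report <- function(object, ...) {
  dat <- tidyr::pivot_longer(
    object$per_repeat,
    cols = c("sensitivity", "specificity", "accuracy"),
    names_to = "metric", values_to = "percent")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$metric, y = .data$percent)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "% across repeats") +
    ggplot2::ylim(0, 100)
}
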