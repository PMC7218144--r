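# End-to-end experiment loop: balance -> grouped split -> features -> train ->
# predict sub-blocks -> majority vote -> metrics.

#' Experiment configuration
#'
#' @param paradigm `"I"` (a single hand-crafted feature), `"II"` (multi-feature
#'   early/late fusion) or `"III"` (one sub-model per story).
#' @param variant Network variant, see [MODEL_VARIANTS].  Paradigm III forces
#'   `PER_STORY`.
#' @param features Time-domain feature name(s); paradigm II defaults to the
#'   top-performing quartet mobility, skew, mean, p2p.
#' @param condition Which blocks carry the classified signal: `"active"`
#'   (default) or `"control"` (the CT control-task twin models).
#' @param window_width,window_stride Sub-block windowing in samples
#'   (default 600 / 100).
#' @param block_duration_s Task block duration in seconds (default 30).
#' @param ar_order AR model order for the frequency path (default 20).
#' @param ar_include_rho Append the innovation variance to the AR vector.
#' @param n_repeats Shuffle-split repeats (default 30).
#' @param test_fraction Held-out channel fraction per class (default 0.2).
#' @param val_fraction Fraction of training channels held out (grouped) for
#'   early stopping; 0 (default) monitors training loss instead.
#' @param epochs,batch_size,lr,patience Training controls.
#' @param hyper Layer hyperparameter overrides, see [model_spec()].
#' @param balance Undersample negatives to a 1:1 class ratio per repeat
#'   (default TRUE).
#' @param seed Master seed; per-repeat seeds are derived from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(paradigm = c("I", "II", "III"),
                              variant = "AT_AR3",
                              features = NULL,
                              condition = c("active", "control"),
                              window_width = 600, window_stride = 100,
                              block_duration_s = 30,
                              ar_order = 20, ar_include_rho = FALSE,
                              n_repeats = 30, test_fraction = 0.2,
                              val_fraction = 0,
                              epochs = 30, batch_size = 32, lr = 1e-3,
                              patience = 10,
                              hyper = list(), balance = TRUE, seed = 1) {
  paradigm <- match.arg(paradigm)
  condition <- match.arg(condition)
  if (paradigm == "III") variant <- "PER_STORY"
  variant <- match.arg(variant, MODEL_VARIANTS)
  if (is.null(features)) {
    features <- switch(paradigm,
                       I = "mobility",
                       II = c("mobility", "skew", "mean", "p2p"),
                       III = "mobility")
  }
  unknown <- setdiff(features, TIME_FEATURES)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown feature(s): %s.", paste(unknown, collapse = ", ")),
          class = "ecogmapr_config_error")
  }
  structure(list(paradigm = paradigm, variant = variant, features = features,
                 condition = condition,
                 window_width = window_width, window_stride = window_stride,
                 block_duration_s = block_duration_s,
                 ar_order = ar_order, ar_include_rho = ar_include_rho,
                 n_repeats = n_repeats, test_fraction = test_fraction,
                 val_fraction = val_fraction,
                 epochs = epochs, batch_size = batch_size, lr = lr,
                 patience = patience, hyper = hyper, balance = balance,
                 seed = seed),
            class = "experiment_config")
}

#' Report label of a network variant
#' @param variant One of [MODEL_VARIANTS].
#' @return Display string (e.g. `"AT-AR3-LF2"`).
#' @export
variant_label <- function(variant) {
  if (variant == "PER_STORY") return("AT-AR3-story")
  gsub("_", "-", variant)
}

#' Extract the time- and frequency-domain features of a whole cohort
#'
#' Runs Steps 1-3 once per channel: trim to the task, cut uniform blocks,
#' window each block and compute the selected per-window features, and fit
#' the per-block AR feature vector.
#'
#' @param recordings List of annotated [ecog_recording()] objects.
#' @param config An [experiment_config()].
#' @return Tibble with one row per (channel, block): `channel_id`, `label`,
#'   `block_idx`, `condition`, `story_id`, and list-columns `time`
#'   (n_windows x n_features matrix) and `ar` (AR feature vector).
#' @export
extract_cohort_features <- function(recordings, config = experiment_config()) {
  purrr::map_dfr(recordings, function(rec) {
    blocks <- extract_blocks(trim_to_task(rec),
                             block_duration_s = config$block_duration_s)
    purrr::map_dfr(seq_len(nrow(blocks)), function(i) {
      ws <- sliding_windows(blocks$samples[[i]], config$window_width,
                            config$window_stride)
      fseq <- build_feature_sequence(ws, config$features)
      arv <- ar_feature_vector(blocks$samples[[i]], p = config$ar_order,
                               include_rho = config$ar_include_rho)
      tibble::tibble(channel_id = rec$channel_id,
                     label = rec$truth_label,
                     block_idx = blocks$block_idx[i],
                     condition = blocks$condition[i],
                     story_id = blocks$story_id[i],
                     time = list(fseq$values),
                     ar = list(arv))
    })
  })
}

# Stack feature-store rows for a set of channels into an nn_dataset.
build_dataset <- function(store, channel_ids, config) {
  rows <- dplyr::filter(store, .data$channel_id %in% channel_ids,
                        .data$condition == config$condition)
  if (nrow(rows) == 0) {
    abort("No feature rows for the requested channels/condition.",
          class = "ecogmapr_validation_error")
  }
  y <- as.numeric(rows$label == "PRC")
  if (config$paradigm == "III") {
    # one instance per channel; one (time, freq) path per story
    chans <- unique(rows$channel_id)
    stories <- sort(unique(rows$story_id))
    time <- lapply(stories, function(s) {
      mats <- lapply(chans, function(ch) {
        rows$time[rows$channel_id == ch & rows$story_id == s][[1]]
      })
      stack_time(mats)
    })
    freq <- lapply(stories, function(s) {
      do.call(rbind, lapply(chans, function(ch) {
        rows$ar[rows$channel_id == ch & rows$story_id == s][[1]]
      }))
    })
    lab <- vapply(chans, function(ch)
      rows$label[rows$channel_id == ch][1], character(1))
    nn_dataset(time, as.numeric(lab == "PRC"), freq = freq,
               meta = tibble::tibble(channel_id = chans, truth = lab))
  } else {
    nn_dataset(stack_time(rows$time), y,
               freq = do.call(rbind, rows$ar),
               meta = tibble::tibble(channel_id = rows$channel_id,
                                     block_idx = rows$block_idx,
                                     story_id = rows$story_id,
                                     truth = rows$label))
  }
}

stack_time <- function(mats) {
  n_win <- min(vapply(mats, nrow, integer(1)))
  arr <- array(0, dim = c(length(mats), n_win, ncol(mats[[1]])))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]][seq_len(n_win), ]
  arr
}

make_model_spec <- function(config, store) {
  rows <- dplyr::filter(store, .data$condition == config$condition)
  n_windows <- min(vapply(rows$time, nrow, integer(1)))
  ar_dim <- length(rows$ar[[1]])
  needs_freq <- !config$variant %in% c("AT1", "AT2")
  model_spec(config$variant, n_windows = n_windows,
             n_features = length(config$features),
             ar_dim = if (needs_freq) ar_dim else NULL,
             n_stories = length(unique(stats::na.omit(rows$story_id))),
             hyper = config$hyper)
}

derive_seed <- function(seed, r) {
  as.integer((as.double(seed) * 10007 + r * 7919) %% 2147483647)
}

#' Run a full channel-classification experiment
#'
#' The complete loop over shuffle-split repeats.  Per repeat (with a derived
#' seed): undersample negatives to balance the classes, hold out a stratified
#' set of whole channels, train the configured network on the training
#' channels' sub-block streams, predict the held-out sub-blocks, majority-vote
#' each test channel, and score.  Features are extracted once up front.
#'
#' @param recordings List of labelled, annotated [ecog_recording()] objects,
#'   or a precomputed feature store from [extract_cohort_features()].
#' @param config An [experiment_config()].
#' @param verbose Print per-repeat progress.
#' @return A `metric_report` with extra fields `config` and `model_label`.
#' @export
run_experiment <- function(recordings, config = experiment_config(),
                           verbose = FALSE) {
  store <- if (inherits(recordings, "data.frame")) {
    recordings
  } else {
    extract_cohort_features(recordings, config)
  }
  manifest <- dplyr::distinct(store, .data$channel_id, .data$label)
  if (!all(manifest$label %in% c("PRC", "NRC"))) {
    abort("Every channel needs a PRC/NRC truth label.",
          class = "ecogmapr_validation_error")
  }
  spec <- make_model_spec(config, store)

  results <- purrr::map_dfr(seq_len(config$n_repeats), function(r) {
    rep_seed <- derive_seed(config$seed, r)
    pool <- if (config$balance) balance_classes(manifest, seed = rep_seed) else manifest
    fold <- grouped_shuffle_split(pool, n_repeats = 1,
                                  test_fraction = config$test_fraction,
                                  seed = rep_seed)
    train_ids <- fold$train[[1]]
    test_ids <- fold$test[[1]]

    val_data <- NULL
    if (config$val_fraction > 0) {
      inner <- grouped_shuffle_split(
        dplyr::filter(pool, .data$channel_id %in% train_ids),
        n_repeats = 1, test_fraction = config$val_fraction,
        seed = derive_seed(rep_seed, 1))
      val_ids <- inner$test[[1]]
      train_ids <- inner$train[[1]]
      val_data <- build_dataset(store, val_ids, config)
    }
    train_data <- build_dataset(store, train_ids, config)
    test_data <- build_dataset(store, test_ids, config)

    model <- build_model(spec, seed = rep_seed)
    model <- train_model(model, train_data,
                         epochs = config$epochs,
                         batch_size = config$batch_size,
                         lr = config$lr, seed = rep_seed,
                         validation = val_data, patience = config$patience)
    preds <- predict_subblocks(model, test_data)
    per_channel <- preds |>
      dplyr::group_by(.data$channel_id, .data$truth) |>
      dplyr::summarise(
        voted_label = majority_vote(.data$label),
        positive_fraction = mean(.data$label == "positive"),
        n_subblocks = dplyr::n(),
        n_subblocks_correct = sum((.data$label == "positive") ==
                                    (.data$truth == "PRC")),
        .groups = "drop") |>
      dplyr::mutate(repeat_idx = r)
    if (verbose) {
      message(sprintf("repeat %2d: channel acc %.1f%%", r,
                      100 * mean(per_channel$voted_label ==
                                   per_channel$truth)))
    }
    per_channel
  })

  report <- compute_metrics(results)
  report$config <- config
  report$model_label <- variant_label(config$variant)
  report
}

#' Write a metric report as a results table
#'
#' One row per model/feature set with block accuracy, sensitivity,
#' specificity and accuracy as `mean +/- sd` strings, TSV format.
#'
#' @param reports A `metric_report` or list of them.
#' @param path Output TSV path.
#' @return Invisibly, the formatted tibble.
#' @export
write_results_table <- function(reports, path) {
  if (inherits(reports, "metric_report")) reports <- list(reports)
  fmt <- function(m, s) ifelse(is.na(m), "-", sprintf("%.2f ± %.2f", m, s))
  tab <- purrr::map_dfr(reports, function(rep) {
    s <- rep$summary
    tibble::tibble(
      model = rep$model_label %||% "model",
      features = paste(rep$config$features %||% "?", collapse = "+"),
      block_accuracy = fmt(s$block_accuracy_mean, s$block_accuracy_sd),
      sensitivity = fmt(s$sensitivity_mean, s$sensitivity_sd),
      specificity = fmt(s$specificity_mean, s$specificity_sd),
      accuracy = fmt(s$accuracy_mean, s$accuracy_sd))
  })
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
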