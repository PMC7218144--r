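# Dataset container, normalisation, training loop and sub-block prediction.

#' Assemble a labelled instance set for the networks
#'
#' One instance is one sub-block stream: the window-by-feature matrix of one
#' task block (plus, for the AR variants, the block's frequency feature
#' vector), labelled with its channel's PRC/NRC status.
#'
#' @param time `B x T x F` array (or, for `PER_STORY`, list of per-story
#'   arrays, one instance per channel).
#' @param y Numeric 0/1 labels (1 = PRC).
#' @param freq `B x P` matrix of AR features (list of matrices for
#'   `PER_STORY`), or `NULL` for time-only variants.
#' @param meta Tibble of per-instance metadata (`channel_id`, `block_idx`,
#'   `story_id`, ...), carried through to predictions.
#' @return An `nn_dataset`.
#' @export
nn_dataset <- function(time, y, freq = NULL, meta = NULL) {
  B <- if (is.list(time)) dim(time[[1]])[1] else dim(time)[1]
  stopifnot(length(y) == B, all(y %in% c(0, 1)))
  if (is.null(meta)) meta <- tibble::tibble(instance = seq_len(B))
  vals <- if (is.list(time)) unlist(lapply(time, as.vector)) else as.vector(time)
  if (!all(is.finite(vals))) {
    abort("nn_dataset: non-finite values in time features.",
          class = "ecogmapr_validation_error")
  }
  if (!is.null(freq)) {
    fv <- if (is.list(freq)) unlist(lapply(freq, as.vector)) else as.vector(freq)
    if (!all(is.finite(fv))) {
      abort("nn_dataset: non-finite values in frequency features.",
            class = "ecogmapr_validation_error")
    }
  }
  structure(list(time = time, freq = freq, y = as.numeric(y),
                 meta = tibble::as_tibble(meta)),
            class = "nn_dataset")
}

#' @export
print.nn_dataset <- function(x, ...) {
  B <- length(x$y)
  cat(sprintf("<nn_dataset> %d instances (%d positive), %s frequency path\n",
              B, sum(x$y), if (is.null(x$freq)) "no" else "with"))
  invisible(x)
}

dataset_slice <- function(data, idx) {
  sl <- function(a) {
    if (is.list(a)) lapply(a, function(x) x[idx, , , drop = FALSE])
    else a[idx, , , drop = FALSE]
  }
  slf <- function(f) {
    if (is.null(f)) NULL
    else if (is.list(f)) lapply(f, function(x) x[idx, , drop = FALSE])
    else f[idx, , drop = FALSE]
  }
  structure(list(time = sl(data$time), freq = slf(data$freq),
                 y = data$y[idx], meta = data$meta[idx, , drop = FALSE]),
            class = "nn_dataset")
}

# Per-feature z-scoring statistics computed from a training set only.
compute_norm <- function(data) {
  time_stats <- function(arrs) {
    if (!is.list(arrs)) arrs <- list(arrs)
    Fh <- dim(arrs[[1]])[3]
    mu <- sigma <- numeric(Fh)
    for (f in seq_len(Fh)) {
      v <- unlist(lapply(arrs, function(a) as.vector(a[, , f])))
      mu[f] <- mean(v)
      s <- sd(v)
      sigma[f] <- if (is.finite(s) && s > 0) s else 1
    }
    list(mu = mu, sigma = sigma)
  }
  freq_stats <- function(fr) {
    if (is.null(fr)) return(NULL)
    if (!is.list(fr)) fr <- list(fr)
    m <- do.call(rbind, fr)
    mu <- colMeans(m)
    sigma <- apply(m, 2, sd)
    sigma[!is.finite(sigma) | sigma == 0] <- 1
    list(mu = mu, sigma = sigma)
  }
  list(time = time_stats(data$time), freq = freq_stats(data$freq))
}

apply_norm <- function(data, norm) {
  zt <- function(a) {
    for (f in seq_len(dim(a)[3])) {
      a[, , f] <- (a[, , f] - norm$time$mu[f]) / norm$time$sigma[f]
    }
    a
  }
  zf <- function(m) sweep(sweep(m, 2, norm$freq$mu), 2, norm$freq$sigma, `/`)
  data$time <- if (is.list(data$time)) lapply(data$time, zt) else zt(data$time)
  if (!is.null(data$freq) && !is.null(norm$freq)) {
    data$freq <- if (is.list(data$freq)) lapply(data$freq, zf) else zf(data$freq)
  }
  data
}

eval_forward <- function(model, data) {
  tape <- nn_tape(training = FALSE)
  logits <- nn_forward(model, data, tape)
  as.vector(stats::plogis(logits$value))
}

bce <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

#' Train a network on labelled sub-block streams
#'
#' Minimises binary cross-entropy with Adam over shuffled mini-batches.
#' Per-feature z-scoring statistics are computed from the training data only,
#' stored in the model, and applied to every later input.  Training stops
#' early when the monitored loss (validation loss if `validation` is given,
#' else training loss) has not improved for `patience` epochs; the best
#' weights are restored.  With a fixed seed and single-threaded BLAS the run
#' is deterministic.
#'
#' @param model An untrained `ecog_model` from [build_model()].
#' @param data Training [nn_dataset()]; must contain both classes.
#' @param epochs Maximum epochs (default 30).
#' @param batch_size Mini-batch size (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed Seed for shuffling and dropout.
#' @param validation Optional held-out `nn_dataset` for early stopping.
#' @param patience Early-stopping patience in epochs (default 10).
#' @param verbose Print per-epoch losses.
#' @return The trained `ecog_model` with a `history` tibble.
#' @export
train_model <- function(model, data, epochs = 30, batch_size = 32, lr = 1e-3,
                        seed = 1, validation = NULL, patience = 10,
                        verbose = FALSE) {
  stopifnot(inherits(model, "ecog_model"), inherits(data, "nn_dataset"))
  if (length(unique(data$y)) < 2) {
    abort("Training data must contain both classes.",
          class = "ecogmapr_validation_error")
  }
  norm <- compute_norm(data)
  data <- apply_norm(data, norm)
  if (!is.null(validation)) validation <- apply_norm(validation, norm)
  params <- flatten_params(model$params)
  B <- length(data$y)
  history <- vector("list", epochs)
  best <- list(loss = Inf, values = NULL, epoch = 0L)
  wait <- 0L
  step <- 0L

  with_rng_seed(seed, {
    for (epoch in seq_len(epochs)) {
      idx <- sample.int(B)
      starts <- seq(1L, B, by = batch_size)
      ep_loss <- 0
      ep_correct <- 0
      for (s in starts) {
        take <- idx[s:min(s + batch_size - 1L, B)]
        batch <- dataset_slice(data, take)
        tape <- nn_tape(training = TRUE)
        logits <- nn_forward(model, batch, tape)
        loss <- op_sigmoid_bce(tape, logits, batch$y)
        if (!is.finite(loss$value)) {
          abort(sprintf("Training diverged (non-finite loss) at epoch %d.", epoch),
                class = "ecogmapr_divergence_error")
        }
        nn_backward(tape, loss)
        step <- step + 1L
        adam_step(params, lr = lr, t = step)
        p_hat <- stats::plogis(as.vector(logits$value))
        ep_loss <- ep_loss + loss$value * length(take)
        ep_correct <- ep_correct + sum((p_hat > 0.5) == (batch$y == 1))
      }
      row <- tibble::tibble(epoch = epoch, loss = ep_loss / B,
                            accuracy = ep_correct / B,
                            val_loss = NA_real_, val_accuracy = NA_real_)
      if (!is.null(validation)) {
        pv <- eval_forward(model, validation)
        row$val_loss <- bce(pv, validation$y)
        row$val_accuracy <- mean((pv > 0.5) == (validation$y == 1))
      }
      history[[epoch]] <- row
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f%s", epoch, row$loss,
                        row$accuracy,
                        if (!is.null(validation))
                          sprintf("  val_loss %.4f  val_acc %.3f",
                                  row$val_loss, row$val_accuracy) else ""))
      }
      monitored <- if (!is.null(validation)) row$val_loss else row$loss
      if (monitored < best$loss - 1e-6) {
        best <- list(loss = monitored, values = param_values(params),
                     epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  })
  if (!is.null(best$values)) set_param_values(params, best$values)
  model$norm <- norm
  model$history <- dplyr::bind_rows(history[!vapply(history, is.null, logical(1))])
  model$best_epoch <- best$epoch
  model$train_seed <- seed
  model$trained <- TRUE
  model
}

#' Per-instance sub-block predictions
#'
#' Runs the network in inference mode (dropout off, stored normalisation
#' applied) and thresholds the sigmoid output at 0.5: an instance is labelled
#' `"positive"` iff its probability exceeds 0.5 (a probability of exactly 0.5
#' is negative — strict rule).
#'
#' @param model A trained `ecog_model`.
#' @param data An [nn_dataset()] (labels may be all zero at prediction time).
#' @return Tibble: the dataset metadata plus `prob` and `label`.
#' @export
predict_subblocks <- function(model, data) {
  stopifnot(inherits(model, "ecog_model"), inherits(data, "nn_dataset"))
  if (!model$trained) {
    warn("Predicting with an untrained model.")
  }
  check_shapes(model$spec, data)
  if (!is.null(model$norm)) data <- apply_norm(data, model$norm)
  prob <- eval_forward(model, data)
  out <- data$meta
  out$prob <- prob
  out$label <- ifelse(prob > 0.5, "positive", "negative")
  out
}

check_shapes <- function(spec, data) {
  dims <- if (is.list(data$time)) dim(data$time[[1]]) else dim(data$time)
  if (dims[2] != spec$n_windows) {
    abort(sprintf("Sequence-length mismatch: model expects %d windows, data has %d.",
                  spec$n_windows, dims[2]),
          class = "ecogmapr_validation_error")
  }
  if (dims[3] != spec$n_features) {
    abort(sprintf("Feature-count mismatch: model expects %d, data has %d.",
                  spec$n_features, dims[3]),
          class = "ecogmapr_validation_error")
  }
  if (!is.null(spec$ar_dim)) {
    if (is.null(data$freq)) {
      abort("This variant needs a frequency path but the dataset has none.",
            class = "ecogmapr_config_error")
    }
    pf <- if (is.list(data$freq)) ncol(data$freq[[1]]) else ncol(data$freq)
    if (pf != spec$ar_dim) {
      abort(sprintf("AR-dimension mismatch: model expects %d, data has %d.",
                    spec$ar_dim, pf),
            class = "ecogmapr_validation_error")
    }
  }
  invisible(TRUE)
}

#' @method tidy ecog_model
#' @export
tidy.ecog_model <- function(x, ...) {
  if (is.null(x$history)) {
    abort("Model has no training history yet.", class = "ecogmapr_validation_error")
  }
  x$history
}

#' @method glance ecog_model
#' @export
glance.ecog_model <- function(x, ...) {
  h <- tidy(x)
  tibble::tibble(variant = x$spec$variant, epochs_run = nrow(h),
                 best_epoch = x$best_epoch,
                 final_loss = h$loss[nrow(h)],
                 final_accuracy = h$accuracy[nrow(h)])
}

#' @method autoplot ecog_model
#' @export
autoplot.ecog_model <- function(object, ...) {
  h <- tidy(object)
  dat <- tidyr::pivot_longer(h, cols = -"epoch",
                             names_to = "metric", values_to = "value")
  dat <- dat[is.finite(dat$value), ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}

# Stable hash of the flattened weights, used to assert determinism.
weights_signature <- function(model) {
  v <- unlist(param_values(flatten_params(model$params)))
  paste0(format(sum(v), digits = 17), ":",
         format(sum(v^2), digits = 17), ":", length(v))
}
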