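#' Network variants
#'
#' The architecture family for channel-response classification.  `AT1` is a
#' fully convolutional time-domain model; `AT2` adds a parallel LSTM path;
#' `AT_AR1`-`AT_AR4` fuse the time-domain trunk with the autoregressive
#' frequency features under increasingly deep fusion heads; `AT_AR3_EF`
#' supplies several hand-crafted features as parallel input channels (early
#' fusion); `AT_AR3_LF1`/`AT_AR3_LF2` train one time-domain sub-model per
#' feature and merge late; `PER_STORY` trains one `AT_AR3` trunk per story and
#' merges through a final fully connected layer.
#' @export
MODEL_VARIANTS <- c("AT1", "AT2", "AT_AR1", "AT_AR2", "AT_AR3", "AT_AR4",
                    "AT_AR3_EF", "AT_AR3_LF1", "AT_AR3_LF2", "PER_STORY")

default_hyper <- function() {
  list(
    conv_filters = c(16L, 32L, 16L),
    conv_kernels = c(8L, 5L, 3L),
    lstm_units = 16L,
    fc_units = 32L,
    freq_units = 16L,
    fusion_conv_filters = c(16L, 16L),
    fusion_conv_kernels = c(3L, 3L),
    dropout = 0.2
  )
}

#' Specify a network
#'
#' @param variant One of [MODEL_VARIANTS].
#' @param n_windows Time-path sequence length (windows per sub-block stream).
#' @param n_features Number of time-domain features (input channels).
#' @param ar_dim Length of the frequency-domain (AR) feature vector; required
#'   by all `AT_AR*` variants and `PER_STORY`, ignored by `AT1`/`AT2`.
#' @param n_stories Number of story sub-models for `PER_STORY` (default 5).
#' @param hyper Named list overriding layer hyperparameters: `conv_filters`,
#'   `conv_kernels`, `lstm_units`, `fc_units`, `freq_units`,
#'   `fusion_conv_filters`, `fusion_conv_kernels`, `dropout`.
#' @return A `model_spec` list.
#' @export
model_spec <- function(variant, n_windows, n_features, ar_dim = NULL,
                       n_stories = 5, hyper = list()) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  needs_freq <- !variant %in% c("AT1", "AT2")
  if (needs_freq && (is.null(ar_dim) || ar_dim < 1)) {
    abort(sprintf("Variant %s needs a frequency path: supply `ar_dim`.", variant),
          class = "ecogmapr_config_error")
  }
  if (!needs_freq) ar_dim <- NULL
  stopifnot(n_windows >= 1, n_features >= 1)
  h <- modifyList(default_hyper(), hyper)
  structure(list(variant = variant,
                 n_windows = as.integer(n_windows),
                 n_features = as.integer(n_features),
                 ar_dim = if (is.null(ar_dim)) NULL else as.integer(ar_dim),
                 n_stories = as.integer(n_stories),
                 hyper = h),
            class = "model_spec")
}

make_dense <- function(n_in, n_out) {
  list(W = nn_param(glorot_init(n_in, n_out)),
       b = nn_param(numeric(n_out)))
}

make_conv <- function(kernel, c_in, c_out) {
  list(W = nn_param(glorot_init(kernel * c_in, c_out)),
       b = nn_param(numeric(c_out)), kernel = as.integer(kernel))
}

make_conv_stack <- function(c_in, filters, kernels) {
  layers <- vector("list", length(filters))
  for (i in seq_along(filters)) {
    layers[[i]] <- make_conv(kernels[i], c_in, filters[i])
    c_in <- filters[i]
  }
  layers
}

make_lstm <- function(c_in, units) {
  b <- numeric(4 * units)
  b[(units + 1):(2 * units)] <- 1   # forget-gate bias
  list(Wx = nn_param(glorot_init(c_in, 4 * units)),
       Wh = nn_param(glorot_init(units, 4 * units)),
       b = nn_param(b), units = as.integer(units))
}

make_freq_module <- function(p, units, depth = 1) {
  layers <- vector("list", depth)
  n_in <- p
  for (i in seq_len(depth)) {
    layers[[i]] <- make_dense(n_in, units)
    n_in <- units
  }
  layers
}

# One conv(+lstm) time trunk for a given number of input channels.
make_time_trunk <- function(c_in, h, with_lstm = TRUE) {
  trunk <- list(conv = make_conv_stack(c_in, h$conv_filters, h$conv_kernels))
  if (with_lstm) trunk$lstm <- make_lstm(c_in, h$lstm_units)
  trunk
}

trunk_width <- function(h, with_lstm = TRUE) {
  tail(h$conv_filters, 1) + if (with_lstm) h$lstm_units else 0L
}

#' Build an untrained network
#'
#' Instantiates the weights of a [model_spec()] with seeded Glorot-uniform
#' initialisation (forget-gate biases start at 1).
#'
#' @param spec A `model_spec`.
#' @param seed Integer seed for weight initialisation.
#' @return An `ecog_model`.
#' @export
build_model <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  h <- spec$hyper
  Fh <- spec$n_features
  params <- with_rng_seed(seed, {
    switch(
      spec$variant,
      AT1 = list(time = list(conv = make_conv_stack(Fh, h$conv_filters, h$conv_kernels)),
                 head = make_dense(tail(h$conv_filters, 1), 1)),
      AT2 = list(time = make_time_trunk(Fh, h),
                 head = make_dense(trunk_width(h), 1)),
      AT_AR1 = list(time = make_time_trunk(Fh, h),
                    freq = make_freq_module(spec$ar_dim, h$freq_units),
                    head = make_dense(trunk_width(h) + h$freq_units, 1)),
      AT_AR2 = list(time = make_time_trunk(Fh, h),
                    freq = make_freq_module(spec$ar_dim, h$freq_units),
                    fusion_conv = make_conv_stack(
                      tail(h$conv_filters, 1) + h$freq_units,
                      h$fusion_conv_filters, h$fusion_conv_kernels),
                    head = make_dense(tail(h$fusion_conv_filters, 1) + h$lstm_units, 1)),
      AT_AR3 = ,
      AT_AR3_EF = list(time = make_time_trunk(Fh, h),
                       freq = make_freq_module(spec$ar_dim, h$freq_units),
                       fusion = make_dense(trunk_width(h) + h$freq_units, h$fc_units),
                       head = make_dense(h$fc_units, 1)),
      AT_AR4 = list(time = make_time_trunk(Fh, h),
                    freq = make_freq_module(spec$ar_dim, h$freq_units, depth = 2),
                    fusion = make_dense(trunk_width(h) + h$freq_units, h$fc_units),
                    head = make_dense(h$fc_units, 1)),
      AT_AR3_LF1 = list(time = lapply(seq_len(Fh), function(i) make_time_trunk(1L, h)),
                        freq = make_freq_module(spec$ar_dim, h$freq_units),
                        fusion = make_dense(Fh * trunk_width(h) + h$freq_units, h$fc_units),
                        head = make_dense(h$fc_units, 1)),
      AT_AR3_LF2 = list(time = lapply(seq_len(Fh), function(i) make_time_trunk(1L, h)),
                        freq = make_freq_module(spec$ar_dim, h$freq_units),
                        per_feature = lapply(seq_len(Fh), function(i)
                          make_dense(trunk_width(h) + h$freq_units, h$fc_units)),
                        fusion = make_dense(Fh * h$fc_units, h$fc_units),
                        head = make_dense(h$fc_units, 1)),
      PER_STORY = list(stories = lapply(seq_len(spec$n_stories), function(s)
                         list(time = make_time_trunk(Fh, h),
                              freq = make_freq_module(spec$ar_dim, h$freq_units),
                              fusion = make_dense(trunk_width(h) + h$freq_units,
                                                  h$fc_units))),
                       head = make_dense(spec$n_stories * h$fc_units, 1))
    )
  })
  structure(list(spec = spec, params = params, norm = NULL, history = NULL,
                 init_seed = seed, trained = FALSE),
            class = "ecog_model")
}

#' @export
print.ecog_model <- function(x, ...) {
  n_par <- sum(vapply(flatten_params(x$params),
                      function(p) length(p$value), numeric(1)))
  cat(sprintf("<ecog_model> %s (%s), %d parameters; time input %d x %d%s\n",
              x$spec$variant, if (x$trained) "trained" else "untrained",
              as.integer(n_par), x$spec$n_windows, x$spec$n_features,
              if (is.null(x$spec$ar_dim)) "" else
                sprintf(", AR input %d", x$spec$ar_dim)))
  invisible(x)
}

## ---- forward graphs --------------------------------------------------------

fwd_conv_stack <- function(tape, x, layers) {
  for (ly in layers) {
    x <- op_relu3(tape, op_conv1d(tape, x, ly$W, ly$b, ly$kernel))
  }
  x
}

fwd_time_trunk <- function(tape, x, trunk) {
  reps <- list(op_gap(tape, fwd_conv_stack(tape, x, trunk$conv)))
  if (!is.null(trunk$lstm)) {
    reps <- c(reps, list(op_lstm_last(tape, x, trunk$lstm$Wx, trunk$lstm$Wh,
                                      trunk$lstm$b)))
  }
  if (length(reps) == 1) reps[[1]] else op_concat(tape, reps)
}

fwd_freq_module <- function(tape, f, layers) {
  for (ly in layers) {
    f <- op_relu(tape, op_dense(tape, f, ly$W, ly$b))
  }
  f
}

# Forward pass to logits. `batch` is a list with elements `time` (B x T x F
# array, or list of such for PER_STORY) and `freq` (B x P matrix or list).
nn_forward <- function(model, batch, tape) {
  p <- model$params
  h <- model$spec$hyper
  variant <- model$spec$variant
  drop <- h$dropout
  logits <- switch(
    variant,
    AT1 = {
      repr <- op_gap(tape, fwd_conv_stack(tape, nn_node(batch$time), p$time$conv))
      op_dense(tape, op_dropout(tape, repr, drop), p$head$W, p$head$b)
    },
    AT2 = {
      repr <- fwd_time_trunk(tape, nn_node(batch$time), p$time)
      op_dense(tape, op_dropout(tape, repr, drop), p$head$W, p$head$b)
    },
    AT_AR1 = {
      tr <- fwd_time_trunk(tape, nn_node(batch$time), p$time)
      fr <- fwd_freq_module(tape, nn_node(batch$freq), p$freq)
      fused <- op_concat(tape, list(tr, fr))
      op_dense(tape, op_dropout(tape, fused, drop), p$head$W, p$head$b)
    },
    AT_AR2 = {
      x <- nn_node(batch$time)
      seq_repr <- fwd_conv_stack(tape, x, p$time$conv)
      fr <- fwd_freq_module(tape, nn_node(batch$freq), p$freq)
      fused_seq <- op_tile_concat(tape, seq_repr, fr)
      conv_repr <- op_gap(tape, fwd_conv_stack(tape, fused_seq, p$fusion_conv))
      lstm_repr <- op_lstm_last(tape, x, p$time$lstm$Wx, p$time$lstm$Wh,
                                p$time$lstm$b)
      fused <- op_concat(tape, list(conv_repr, lstm_repr))
      op_dense(tape, op_dropout(tape, fused, drop), p$head$W, p$head$b)
    },
    AT_AR3 = ,
    AT_AR3_EF = ,
    AT_AR4 = {
      tr <- fwd_time_trunk(tape, nn_node(batch$time), p$time)
      fr <- fwd_freq_module(tape, nn_node(batch$freq), p$freq)
      fused <- op_concat(tape, list(tr, fr))
      hid <- op_relu(tape, op_dense(tape, fused, p$fusion$W, p$fusion$b))
      op_dense(tape, op_dropout(tape, hid, drop), p$head$W, p$head$b)
    },
    AT_AR3_LF1 = {
      Fh <- model$spec$n_features
      reps <- lapply(seq_len(Fh), function(i) {
        xi <- batch$time[, , i, drop = FALSE]
        fwd_time_trunk(tape, nn_node(xi), p$time[[i]])
      })
      fr <- fwd_freq_module(tape, nn_node(batch$freq), p$freq)
      fused <- op_concat(tape, c(reps, list(fr)))
      hid <- op_relu(tape, op_dense(tape, fused, p$fusion$W, p$fusion$b))
      op_dense(tape, op_dropout(tape, hid, drop), p$head$W, p$head$b)
    },
    AT_AR3_LF2 = {
      Fh <- model$spec$n_features
      fr <- fwd_freq_module(tape, nn_node(batch$freq), p$freq)
      reps <- lapply(seq_len(Fh), function(i) {
        xi <- batch$time[, , i, drop = FALSE]
        tr <- fwd_time_trunk(tape, nn_node(xi), p$time[[i]])
        fused_i <- op_concat(tape, list(tr, fr))
        op_relu(tape, op_dense(tape, fused_i, p$per_feature[[i]]$W,
                               p$per_feature[[i]]$b))
      })
      merged <- op_concat(tape, reps)
      hid <- op_relu(tape, op_dense(tape, merged, p$fusion$W, p$fusion$b))
      op_dense(tape, op_dropout(tape, hid, drop), p$head$W, p$head$b)
    },
    PER_STORY = {
      S <- model$spec$n_stories
      reps <- lapply(seq_len(S), function(s) {
        ps <- p$stories[[s]]
        tr <- fwd_time_trunk(tape, nn_node(batch$time[[s]]), ps$time)
        fr <- fwd_freq_module(tape, nn_node(batch$freq[[s]]), ps$freq)
        fused <- op_concat(tape, list(tr, fr))
        op_relu(tape, op_dense(tape, fused, ps$fusion$W, ps$fusion$b))
      })
      merged <- op_concat(tape, reps)
      op_dense(tape, op_dropout(tape, merged, drop), p$head$W, p$head$b)
    }
  )
  logits
}

#' Concatenate time- and frequency-domain representations
#'
#' Domain fusion is concatenation along the feature axis — never stacking or
#' element-wise multiplication.  A per-instance time representation
#' (`B x F_t` matrix) gains the frequency vector as extra columns; a sequence
#' representation (`B x T x C` array) gets the frequency vector tiled along
#' the time axis.  Argument order is fixed: time first, frequency second.
#'
#' @param time_repr `B x F_t` matrix or `B x T x C` array.
#' @param freq_repr `B x P` matrix (or length-P vector for a single instance).
#' @return Matrix `B x (F_t + P)` or array `B x T x (C + P)`.
#' @export
fuse_domains <- function(time_repr, freq_repr) {
  if (is.null(dim(freq_repr))) freq_repr <- matrix(freq_repr, nrow = 1)
  if (!all(is.finite(time_repr)) || !all(is.finite(freq_repr))) {
    abort("fuse_domains: inputs must be finite.", class = "ecogmapr_validation_error")
  }
  if (length(dim(time_repr)) == 3) {
    dims <- dim(time_repr)
    if (nrow(freq_repr) != dims[1]) {
      abort("fuse_domains: batch sizes differ.", class = "ecogmapr_validation_error")
    }
    P <- ncol(freq_repr)
    out <- array(0, dim = c(dims[1], dims[2], dims[3] + P))
    out[, , seq_len(dims[3])] <- time_repr
    out[, , dims[3] + seq_len(P)] <-
      aperm(array(freq_repr, dim = c(dims[1], P, dims[2])), c(1, 3, 2))
    out
  } else {
    time_repr <- as.matrix(time_repr)
    if (nrow(freq_repr) != nrow(time_repr)) {
      abort("fuse_domains: batch sizes differ.", class = "ecogmapr_validation_error")
    }
    cbind(time_repr, freq_repr)
  }
}
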