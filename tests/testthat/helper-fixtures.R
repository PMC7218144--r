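# Shared fixtures: everything is generated in code at test time.

# Desk-scale synthetic configuration: short blocks, reduced sampling rate
# (band 70-170 Hz still inside Nyquist at 600 Hz).
tiny_cfg <- function(...) {
  args <- list(fs = 600, block_duration_s = 2, n_prc = 4, n_nrc = 12,
               seed = 99)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

# Matching experiment configuration for the tiny paradigm.
tiny_ec <- function(...) {
  args <- list(window_width = 120, window_stride = 60,
               block_duration_s = 2, ar_order = 8,
               n_repeats = 2, epochs = 8, patience = 20,
               hyper = list(conv_filters = c(6L, 6L),
                            conv_kernels = c(5L, 3L),
                            lstm_units = 4L, fc_units = 8L,
                            freq_units = 6L,
                            fusion_conv_filters = c(6L, 6L),
                            fusion_conv_kernels = c(3L, 3L)),
               seed = 3)
  do.call(experiment_config, utils::modifyList(args, list(...)))
}

# A hand-made two-block recording with lead-in/tail padding.
padded_recording <- function(fs = 100, lead = 37, tail_n = 21) {
  len <- 2 * fs  # two 1 s blocks
  ann <- tibble::tibble(condition = c("control", "active"),
                        story_id = c(NA_integer_, 1L),
                        start_sample = c(lead, lead + fs),
                        end_sample = c(lead + fs, lead + len))
  ecog_recording("pad", rnorm(lead + len + tail_n), fs,
                 annotations = ann, truth_label = "PRC")
}

# Linearly separable toy instance set for capacity/training checks.
toy_dataset <- function(n_per_class = 10, T_ = 20, Fh = 1, P = 4, shift = 2,
                        seed = 1, stories = NULL) {
  withr::local_seed(seed)
  B <- 2 * n_per_class
  y <- rep(c(0, 1), each = n_per_class)
  mk_time <- function() {
    arr <- array(rnorm(B * T_ * Fh), dim = c(B, T_, Fh))
    arr[y == 1, , ] <- arr[y == 1, , ] + shift
    arr
  }
  mk_freq <- function() {
    m <- matrix(rnorm(B * P), B, P)
    m[y == 1, ] <- m[y == 1, ] + shift
    m
  }
  if (is.null(stories)) {
    nn_dataset(mk_time(), y, freq = mk_freq())
  } else {
    nn_dataset(lapply(seq_len(stories), function(s) mk_time()), y,
               freq = lapply(seq_len(stories), function(s) mk_freq()))
  }
}

tiny_hyper <- function() {
  list(conv_filters = c(4L, 4L), conv_kernels = c(3L, 3L), lstm_units = 3L,
       fc_units = 6L, freq_units = 4L, fusion_conv_filters = c(4L, 4L),
       fusion_conv_kernels = c(3L, 3L), dropout = 0)
}
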