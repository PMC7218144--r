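#' Per-window moment statistics
#'
#' The four basic time-domain descriptors of one sub-block window: arithmetic
#' mean, Fisher skewness (third standardised moment, plain moment form),
#' excess kurtosis (fourth standardised moment minus 3) and peak-to-peak
#' amplitude.  Zero-variance windows return skew = 0 and kurtosis = 0 by
#' convention.
#'
#' @param w Numeric vector, one window (length >= 2).
#' @return Named numeric vector `c(mean, skew, kurtosis, p2p)`.
#' @export
window_stats <- function(w) {
  w <- as.double(w)
  if (length(w) < 2) {
    abort("window_stats needs at least 2 samples.", class = "ecogmapr_validation_error")
  }
  m <- mean(w)
  d <- w - m
  m2 <- mean(d^2)
  if (m2 > 0) {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  c(mean = m, skew = skew, kurtosis = kurt, p2p = max(w) - min(w))
}

#' Hjorth parameters of one window
#'
#' The classical trio of time-domain EEG descriptors: activity (signal
#' variance, population form), mobility (the ratio
#' `sqrt(var(diff(w)) / var(w))`, a proxy for mean frequency) and complexity
#' (`mobility(diff(w)) / mobility(w)`, a bandwidth proxy).  First differences
#' stand in for the derivative with no sampling-rate scaling; the constant
#' cancels in complexity and mobility is used as a relative feature.
#'
#' @param w Numeric vector, one window (length >= 3, non-constant).
#' @return Named numeric vector `c(activity, mobility, complexity)`.
#' @export
hjorth_parameters <- function(w) {
  w <- as.double(w)
  if (length(w) < 3) {
    abort("hjorth_parameters needs at least 3 samples.",
          class = "ecogmapr_validation_error")
  }
  varp <- function(x) mean((x - mean(x))^2)
  v0 <- varp(w)
  if (v0 <= 0) {
    abort("hjorth_parameters: zero-variance (constant) window.",
          class = "ecogmapr_degenerate_error")
  }
  d1 <- diff(w)
  d2 <- diff(d1)
  v1 <- varp(d1)
  v2 <- varp(d2)
  mob <- sqrt(v1 / v0)
  mob_d <- if (v1 > 0) sqrt(v2 / v1) else 0
  c(activity = v0, mobility = mob,
    complexity = if (mob > 0) mob_d / mob else 0)
}

#' Supported time-domain feature names
#' @export
TIME_FEATURES <- c("mean", "skew", "kurtosis", "p2p",
                   "activity", "mobility", "complexity")

# Vectorised feature computation over the columns of a width x n window matrix.
# Population (1/N) moments throughout, matching window_stats/hjorth_parameters.
window_feature_matrix <- function(windows, feature_names) {
  n <- ncol(windows)
  width <- nrow(windows)
  mu <- colMeans(windows)
  d <- windows - rep(mu, each = width)
  m2 <- colMeans(d^2)
  out <- matrix(NA_real_, nrow = n, ncol = length(feature_names),
                dimnames = list(NULL, feature_names))
  pos <- m2 > 0
  for (f in feature_names) {
    out[, f] <- switch(
      f,
      mean = mu,
      p2p = apply(windows, 2, max) - apply(windows, 2, min),
      skew = ifelse(pos, colMeans(d^3) / pmax(m2, .Machine$double.xmin)^1.5, 0),
      kurtosis = ifelse(pos, colMeans(d^4) / pmax(m2, .Machine$double.xmin)^2 - 3, 0),
      activity = m2,
      mobility = ,
      complexity = {
        d1 <- apply(windows, 2, diff)
        v1 <- colMeans(d1^2) - colMeans(d1)^2
        if (f == "mobility") {
          ifelse(pos, sqrt(v1 / pmax(m2, .Machine$double.xmin)), NA_real_)
        } else {
          d2 <- apply(d1, 2, diff)
          v2 <- colMeans(d2^2) - colMeans(d2)^2
          mob <- sqrt(v1 / pmax(m2, .Machine$double.xmin))
          mob_d <- ifelse(v1 > 0, sqrt(v2 / pmax(v1, .Machine$double.xmin)), 0)
          ifelse(pos, ifelse(mob > 0, mob_d / mob, 0), NA_real_)
        }
      },
      abort(sprintf("Unknown feature '%s'. Supported: %s.", f,
                    paste(TIME_FEATURES, collapse = ", ")),
            class = "ecogmapr_config_error")
    )
  }
  out
}

#' Build the per-window feature sequence of one block
#'
#' Row `i` holds the selected features of window `i`, in `feature_names`
#' column order — the sub-block stream that feeds the time-domain network.
#' Windows whose Hjorth parameters are degenerate (constant signal) are
#' dropped by default, or filled with a configured value.
#'
#' @param ws A `window_set` from [sliding_windows()].
#' @param feature_names Non-empty subset of
#'   `r paste0('\x60', TIME_FEATURES, '\x60', collapse = ", ")`.
#' @param degenerate One of `"skip"` (drop offending windows, default) or a
#'   numeric fill value for degenerate Hjorth entries.
#' @return A `feature_sequence`: list with `values` (n_windows x n_features
#'   matrix), `feature_names`, `start_indices`.
#' @export
build_feature_sequence <- function(ws, feature_names = TIME_FEATURES,
                                   degenerate = "skip") {
  stopifnot(inherits(ws, "window_set"))
  if (length(feature_names) == 0) {
    abort("`feature_names` must be non-empty.", class = "ecogmapr_config_error")
  }
  unknown <- setdiff(feature_names, TIME_FEATURES)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown feature name(s): %s.", paste(unknown, collapse = ", ")),
          class = "ecogmapr_config_error")
  }
  vals <- window_feature_matrix(ws$windows, feature_names)
  starts <- ws$start_indices
  bad <- which(!stats::complete.cases(vals))
  if (length(bad) > 0) {
    if (identical(degenerate, "skip")) {
      vals <- vals[-bad, , drop = FALSE]
      starts <- starts[-bad]
    } else if (is.numeric(degenerate)) {
      vals[is.na(vals)] <- degenerate
    } else {
      abort("`degenerate` must be \"skip\" or a numeric fill value.",
            class = "ecogmapr_config_error")
    }
  }
  structure(list(values = vals, feature_names = feature_names,
                 start_indices = starts),
            class = "feature_sequence")
}

#' @export
print.feature_sequence <- function(x, ...) {
  cat(sprintf("<feature_sequence> %d windows x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' @method tidy feature_sequence
#' @export
tidy.feature_sequence <- function(x, ...) {
  out <- tibble::as_tibble(x$values)
  out$window <- seq_len(nrow(out))
  out$start_sample <- x$start_indices
  tidyr::pivot_longer(out, cols = -c("window", "start_sample"),
                      names_to = "feature", values_to = "value")
}

#' Plot a feature sequence as per-feature traces
#'
#' @param object A `feature_sequence`.
#' @param ... Unused.
#' @return A ggplot object (one facet per feature over window index).
#' @method autoplot feature_sequence
#' @export
autoplot.feature_sequence <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$window, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "window (sub-block index)", y = NULL)
}
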