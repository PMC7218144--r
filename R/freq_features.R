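#' Fit an autoregressive model by Burg reflection-coefficient estimation
#'
#' Fits the AR model `x[n] = -sum_k a[k] x[n-k] + w[n]` (so the polynomial
#' `A(z) = 1 + a[1] z^-1 + ... + a[p] z^-p` whitens the signal and `w` is a
#' zero-mean white-noise innovation of variance `rho`).  Reflection
#' coefficients are estimated stage by stage by Burg's method — minimising the
#' summed forward and backward prediction-error power — and converted to AR
#' coefficients through the Levinson–Durbin recursion.  Burg guarantees
#' `|k_m| <= 1` (a stable model) and `rho` is non-increasing in the order.
#'
#' Note the sign convention: for a process generated as
#' `x[n] = 0.9 x[n-1] + w[n]`, the fitted coefficient is `a[1] ~ -0.9`
#' (use [ar_conventional()] for the opposite, `stats::ar`-style signs).
#'
#' @param x Numeric signal (length > 2p, non-constant).
#' @param p Model order (positive integer).
#' @param demean Subtract the sample mean first (default `TRUE`; the model
#'   assumes a zero-mean process).
#' @return An `ar_model`: list with `order`, `a` (length p), `rho` (innovation
#'   variance at order p), `reflection` (k_1..k_p), `rho_path` (rho at orders
#'   0..p) and `n`.
#' @export
fit_ar_reflection <- function(x, p, demean = TRUE) {
  x <- as.double(x)
  n <- length(x)
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p != round(p)) {
    abort("`p` must be a positive integer.", class = "ecogmapr_validation_error")
  }
  p <- as.integer(p)
  if (n <= 2L * p) {
    abort(sprintf("AR order %d too large for %d samples (need n > 2p).", p, n),
          class = "ecogmapr_validation_error")
  }
  if (demean) x <- x - mean(x)
  if (mean(x^2) == 0) {
    abort("Cannot fit an AR model to a zero-variance signal.",
          class = "ecogmapr_degenerate_error")
  }

  ef <- eb <- x
  rho <- mean(x^2)
  rho_path <- numeric(p + 1L)
  rho_path[1] <- rho
  a <- numeric(0)
  k <- numeric(p)
  for (m in seq_len(p)) {
    f <- ef[-1L]
    b <- eb[-length(eb)]
    denom <- sum(f^2) + sum(b^2)
    km <- if (denom > 0) -2 * sum(f * b) / denom else 0
    k[m] <- km
    a <- c(a + km * rev(a), km)
    rho <- rho * (1 - km^2)
    rho_path[m + 1L] <- rho
    ef <- f + km * b
    eb <- b + km * f
  }
  structure(list(order = p, a = a, rho = rho, reflection = k,
                 rho_path = rho_path, n = n),
            class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<ar_model> order %d fitted on %d samples; rho = %.4g\n",
              x$order, x$n, x$rho))
  cat("a:", format(round(x$a, 4)), "\n")
  invisible(x)
}

#' Convert fitted coefficients to the regression sign convention
#'
#' Returns `phi` such that `x[n] = sum_k phi[k] x[n-k] + w[n]` (the
#' `stats::ar` convention), i.e. `phi = -a`.
#'
#' @param model An `ar_model`.
#' @return Numeric vector of length `order`.
#' @export
ar_conventional <- function(model) {
  stopifnot(inherits(model, "ar_model"))
  -model$a
}

#' @method tidy ar_model
#' @export
tidy.ar_model <- function(x, ...) {
  tibble::tibble(
    term = paste0("a", seq_len(x$order)),
    estimate = x$a,
    reflection = x$reflection
  )
}

#' @method glance ar_model
#' @export
glance.ar_model <- function(x, ...) {
  tibble::tibble(order = x$order, rho = x$rho, n = x$n,
                 aic = x$n * log(x$rho) + 2 * x$order)
}

#' Power spectral density implied by a fitted AR model
#'
#' One-sided PSD `S(f) = 2 rho / (fs |A(e^{i 2 pi f / fs})|^2)` for
#' `f in [0, fs/2]`; its integral over the half band equals the modelled
#' signal variance.
#'
#' @param model An `ar_model`.
#' @param fs Sampling rate in Hz.
#' @param n_freq Number of evaluation frequencies (default 512).
#' @return Tibble with columns `freq`, `psd`.
#' @export
ar_spectrum <- function(model, fs, n_freq = 512) {
  stopifnot(inherits(model, "ar_model"))
  f <- seq(0, fs / 2, length.out = n_freq)
  omega <- 2 * pi * f / fs
  A <- vapply(omega, function(w)
    abs(1 + sum(model$a * exp(-1i * w * seq_len(model$order)))), numeric(1))
  tibble::tibble(freq = f, psd = 2 * model$rho / (fs * A^2))
}

#' @method autoplot ar_model
#' @export
autoplot.ar_model <- function(object, fs = 1, ...) {
  dat <- ar_spectrum(object, fs = fs)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$freq, y = .data$psd)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "AR model PSD")
}

#' Select an AR model order
#'
#' Chooses among candidate orders by an information criterion computed from
#' the Burg prediction-error power path: `aic` minimises
#' `n log(rho_p) + 2 p`, `fpe` minimises `rho_p (n + p + 1) / (n - p - 1)`,
#' and `fixed` returns `fixed_order` untouched.
#'
#' @param x Numeric signal.
#' @param candidate_orders Non-empty vector of positive integers.
#' @param criterion `"aic"`, `"fpe"` or `"fixed"`.
#' @param fixed_order Order returned when `criterion = "fixed"` (default 20).
#' @return The selected order (integer).
#' @export
select_ar_order <- function(x, candidate_orders = 1:30,
                            criterion = c("aic", "fpe", "fixed"),
                            fixed_order = 20) {
  criterion <- match.arg(criterion)
  if (criterion == "fixed") return(as.integer(fixed_order))
  if (length(candidate_orders) == 0) {
    abort("`candidate_orders` must be non-empty.", class = "ecogmapr_config_error")
  }
  candidate_orders <- sort(unique(as.integer(candidate_orders)))
  p_max <- max(candidate_orders)
  fit <- fit_ar_reflection(x, p_max)
  n <- fit$n
  rho_p <- fit$rho_path[candidate_orders + 1L]
  score <- switch(criterion,
                  aic = n * log(rho_p) + 2 * candidate_orders,
                  fpe = rho_p * (n + candidate_orders + 1) / (n - candidate_orders - 1))
  candidate_orders[which.min(score)]
}

#' Frequency-domain feature vector of one block
#'
#' The AR coefficients of one task block (optionally with the innovation
#' variance appended), the Step-3 characterisation of the signal spectrum.
#' One vector is fitted per 30 s block, not per sub-block window — a 600
#' sample window cannot support a high-order fit.
#'
#' @param block Numeric vector, one block's samples.
#' @param p AR order (default 20).
#' @param include_rho Append `rho` to the feature vector (default `FALSE`).
#' @return Named numeric vector (`a1..ap`, optionally `rho`).
#' @export
ar_feature_vector <- function(block, p = 20, include_rho = FALSE) {
  fit <- fit_ar_reflection(block, p)
  out <- setNames(fit$a, paste0("a", seq_len(p)))
  if (include_rho) out <- c(out, rho = fit$rho)
  out
}
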