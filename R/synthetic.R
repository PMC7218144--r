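#' Synthetic cohort configuration
#'
#' Parameters of the synthetic ECoG generator that stands in for clinical
#' story-listening recordings.  Every channel gets 10 alternating 30 s blocks
#' (control first) at 1200 Hz.  Control blocks (and all blocks of negative
#' channels) are a stationary colored-noise baseline: a first-order
#' autoregressive process with per-channel jittered pole and gain, giving the
#' 1/f-like spectrum of broadband cortical activity.  Active blocks of
#' positive channels additionally receive band-limited noise in `effect_band`
#' (default the high-gamma 70-170 Hz range) scaled so the block's band power
#' is `effect_gain` times the baseline band power, with per-story amplitude
#' jitter.  The cohort-level class ratio defaults to 3 negative channels per
#' positive one.
#'
#' @param fs Sampling rate in Hz (default 1200).
#' @param block_duration_s Block length in seconds (default 30).
#' @param n_active,n_control Active/control blocks per channel (default 5/5).
#' @param n_prc,n_nrc Positive/negative channels in the cohort (default 10/30).
#' @param effect_band Frequency band of the task effect, Hz (default c(70, 170)).
#' @param effect_gain Multiplier `g` on band power in positive active blocks
#'   (default 4; `g = 1` is the null generator).
#' @param power_neutral If `TRUE`, positive active blocks are rescaled to the
#'   baseline block variance, so only the spectral shape (not total power)
#'   carries the effect.
#' @param story_jitter Relative s.d. of per-story effect amplitude (default 0.1).
#' @param baseline_phi AR(1) pole of the baseline process (default 0.95).
#' @param baseline_jitter Per-channel s.d. of the pole (default 0.005).
#' @param gain_jitter Per-channel log-normal amplitude jitter s.d. (default 0.1).
#' @param noise_floor Innovation variance of the baseline process (default 100,
#'   i.e. a baseline rms of tens of microvolts).
#' @param seed Cohort seed; per-channel seeds are derived from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(fs = 1200, block_duration_s = 30,
                             n_active = 5, n_control = 5,
                             n_prc = 10, n_nrc = 30,
                             effect_band = c(70, 170), effect_gain = 4,
                             power_neutral = FALSE,
                             story_jitter = 0.1,
                             baseline_phi = 0.95, baseline_jitter = 0.005,
                             gain_jitter = 0.1, noise_floor = 100,
                             seed = 1) {
  cfg <- list(fs = fs, block_duration_s = block_duration_s,
              n_active = n_active, n_control = n_control,
              n_prc = n_prc, n_nrc = n_nrc,
              effect_band = effect_band, effect_gain = effect_gain,
              power_neutral = power_neutral,
              story_jitter = story_jitter,
              baseline_phi = baseline_phi, baseline_jitter = baseline_jitter,
              gain_jitter = gain_jitter, noise_floor = noise_floor,
              seed = seed)
  if (fs <= 0 || block_duration_s <= 0 || n_prc < 0 || n_nrc < 0) {
    abort("fs and block_duration_s must be positive; channel counts >= 0.",
          class = "ecogmapr_config_error")
  }
  if (effect_gain <= 0) {
    abort("`effect_gain` must be > 0.", class = "ecogmapr_config_error")
  }
  if (effect_band[1] <= 0 || effect_band[2] >= fs / 2 ||
      effect_band[2] <= effect_band[1]) {
    abort(sprintf("`effect_band` must lie within (0, fs/2) = (0, %g).", fs / 2),
          class = "ecogmapr_config_error")
  }
  structure(cfg, class = "synthetic_config")
}

# Fraction of baseline AR(1) power inside [lo, hi] Hz (numerical integral of
# the one-sided PSD on a fine grid).
ar1_band_fraction <- function(phi, fs, lo, hi, n_grid = 4096) {
  f <- seq(0, fs / 2, length.out = n_grid)
  S <- 1 / abs(1 - phi * exp(-2i * pi * f / fs))^2
  df <- f[2] - f[1]
  sum(S[f >= lo & f <= hi]) / sum(S)
}

ar1_block <- function(n, phi, innov_sd, burn = 500) {
  w <- rnorm(n + burn, sd = innov_sd)
  x <- as.numeric(stats::filter(w, phi, method = "recursive"))
  x[(burn + 1):(burn + n)]
}

band_limited_noise <- function(n, fs, band, pad = 500) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  z <- signal::filtfilt(bf, rnorm(n + 2 * pad))
  z[(pad + 1):(pad + n)]
}

#' Generate one synthetic channel
#'
#' Fully seed-deterministic: the same `(label, cfg, seed)` triple yields a
#' bit-identical recording.
#'
#' @param label `"PRC"` or `"NRC"`.
#' @param cfg A [synthetic_config()].
#' @param seed Integer channel seed.
#' @param channel_id Channel name (default derived from the seed).
#' @return An [ecog_recording()] with 10-block annotations and `truth_label`.
#' @export
generate_channel <- function(label, cfg, seed,
                             channel_id = sprintf("ch_%d", seed)) {
  stopifnot(inherits(cfg, "synthetic_config"), label %in% c("PRC", "NRC"))
  n_blk <- as.integer(round(cfg$block_duration_s * cfg$fs))
  ann <- task_annotations(cfg$fs, cfg$block_duration_s, cfg$n_active, cfg$n_control)
  samples <- with_rng_seed(seed, {
    phi <- min(max(cfg$baseline_phi + rnorm(1, 0, cfg$baseline_jitter), 0), 0.995)
    gain <- exp(rnorm(1, 0, cfg$gain_jitter))
    story_mult <- pmax(0.1, 1 + rnorm(cfg$n_active, 0, cfg$story_jitter))
    innov_sd <- gain * sqrt(cfg$noise_floor)
    base_var <- innov_sd^2 / (1 - phi^2)
    band_frac <- ar1_band_fraction(phi, cfg$fs, cfg$effect_band[1], cfg$effect_band[2])
    out <- vector("list", nrow(ann))
    for (i in seq_len(nrow(ann))) {
      x <- ar1_block(n_blk, phi, innov_sd)
      boosted <- ann$condition[i] == "active" && label == "PRC" &&
        cfg$effect_gain != 1
      if (boosted) {
        v_before <- mean((x - mean(x))^2)
        target <- (cfg$effect_gain - 1) * band_frac * base_var *
          story_mult[ann$story_id[i]]
        z <- band_limited_noise(n_blk, cfg$fs, cfg$effect_band)
        z <- z * sqrt(target / mean((z - mean(z))^2))
        x <- x + z
        if (cfg$power_neutral) {
          # restore the block's own pre-boost variance: only the spectral
          # shape carries the effect
          x <- x * sqrt(v_before / mean((x - mean(x))^2))
        }
      }
      out[[i]] <- x
    }
    unlist(out)
  })
  ecog_recording(channel_id, samples, cfg$fs, annotations = ann,
                 truth_label = label)
}

#' Generate a synthetic cohort
#'
#' Positive channels first, then negatives, each with a distinct seed derived
#' from `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `recordings` (list of [ecog_recording()]) and `manifest`
#'   (tibble `channel_id`, `label`, `seed`).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_prc + cfg$n_nrc
  if (n < 2) {
    abort("A cohort needs at least 2 channels.", class = "ecogmapr_config_error")
  }
  labels <- c(rep("PRC", cfg$n_prc), rep("NRC", cfg$n_nrc))
  seeds <- with_rng_seed(cfg$seed, sample.int(.Machine$integer.max - 1L, n))
  ids <- sprintf("ch%03d", seq_len(n))
  recordings <- purrr::pmap(list(labels, seeds, ids), function(lab, s, id) {
    generate_channel(lab, cfg, seed = s, channel_id = id)
  })
  list(recordings = recordings,
       manifest = tibble::tibble(channel_id = ids, label = labels, seed = seeds))
}

## ---- spectral validation helpers ------------------------------------------

#' Welch power spectral density
#'
#' Hann-windowed, 50%-overlap averaged periodogram, one-sided and scaled so
#' that the integral of the PSD over frequency equals the signal variance.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length (default `min(length(x), 1024)`).
#' @return Tibble with columns `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, nperseg = min(length(x), 1024)) {
  x <- as.double(x)
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  scale <- fs * sum(w^2)
  acc <- numeric(nperseg %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(nperseg %/% 2L + 1L)]
    acc <- acc + Mod(X)^2 / scale
  }
  psd <- acc / length(starts)
  psd[c(-1, -length(psd))] <- 2 * psd[c(-1, -length(psd))]
  tibble::tibble(freq = seq(0, fs / 2, length.out = nperseg %/% 2L + 1L),
                 psd = psd)
}

band_integral <- function(psd_tbl, lo, hi) {
  sel <- psd_tbl$freq >= lo & psd_tbl$freq <= hi
  df <- psd_tbl$freq[2] - psd_tbl$freq[1]
  sum(psd_tbl$psd[sel]) * df
}

#' Per-block band-power table and the conventional band-power detector
#'
#' Integrates the Welch PSD of every task block over the given bands — the
#' conventional spectral view of the task effect, used to validate the
#' generator and as a baseline comparison method.
#'
#' @param rec An annotated [ecog_recording()].
#' @param bands Named list of `c(lo, hi)` bands in Hz (default high-gamma
#'   70-170).
#' @return Tibble: `block_idx`, `condition`, `story_id`, `band`, `power`.
#' @export
band_power_summary <- function(rec, bands = list(high_gamma = c(70, 170))) {
  stopifnot(is_ecog_recording(rec))
  for (b in bands) {
    if (b[1] <= 0 || b[2] >= rec$fs / 2) {
      abort(sprintf("Band (%g, %g) outside (0, fs/2).", b[1], b[2]),
            class = "ecogmapr_validation_error")
    }
  }
  blocks <- extract_blocks(trim_to_task(rec), block_duration_s = NULL)
  purrr::map_dfr(seq_len(nrow(blocks)), function(i) {
    psd <- welch_psd(blocks$samples[[i]], rec$fs)
    tibble::tibble(block_idx = i,
                   condition = blocks$condition[i],
                   story_id = blocks$story_id[i],
                   band = names(bands),
                   power = vapply(bands, function(b)
                     band_integral(psd, b[1], b[2]), numeric(1)))
  })
}

#' Conventional band-power channel detector
#'
#' Flags a channel as a positive responder when its active-block band power
#' significantly exceeds its control-block band power (one-sided Wilcoxon
#' rank-sum across blocks) — the classical within-channel baseline-contrast
#' approach the learned pipeline is compared against.
#'
#' @param rec An annotated [ecog_recording()].
#' @param band `c(lo, hi)` in Hz (default 70-170).
#' @param alpha Significance level (default 0.05).
#' @return Tibble: `channel_id`, `p_value`, `detected` (`"PRC"`/`"NRC"`).
#' @export
conventional_detector <- function(rec, band = c(70, 170), alpha = 0.05) {
  bp <- band_power_summary(rec, bands = list(band = band))
  act <- bp$power[bp$condition == "active"]
  ctl <- bp$power[bp$condition == "control"]
  p <- stats::wilcox.test(act, ctl, alternative = "greater", exact = TRUE)$p.value
  tibble::tibble(channel_id = rec$channel_id, p_value = p,
                 detected = ifelse(p < alpha, "PRC", "NRC"))
}
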