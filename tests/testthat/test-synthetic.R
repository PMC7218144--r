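test_that("generated channels have the paradigm's exact geometry", {
  cfg <- tiny_cfg()
  rec <- generate_channel("PRC", cfg, seed = 41)
  expect_length(rec$samples, 10 * 2 * 600)
  expect_identical(nrow(rec$annotations), 10L)
  expect_identical(rec$annotations$condition, rep(c("control", "active"), 5))
  expect_identical(rec$annotations$story_id[c(2, 4, 6, 8, 10)], 1:5)
  expect_identical(rec$truth_label, "PRC")
  # full-rate geometry: 360,000 samples per channel at defaults
  cfg_full <- synthetic_config(n_prc = 1, n_nrc = 1)
  expect_length(generate_channel("NRC", cfg_full, seed = 1)$samples, 360000)
})

test_that("generation is bit-deterministic in the seed", {
  cfg <- tiny_cfg()
  a <- generate_channel("PRC", cfg, seed = 7)
  b <- generate_channel("PRC", cfg, seed = 7)
  c <- generate_channel("PRC", cfg, seed = 8)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c$samples))
})

test_that("cohorts honour the 3:1 class ratio with distinct per-channel seeds", {
  cfg <- tiny_cfg()
  coh <- generate_cohort(cfg)
  expect_length(coh$recordings, 16)
  expect_identical(sum(coh$manifest$label == "NRC"),
                   3L * sum(coh$manifest$label == "PRC"))
  expect_false(anyDuplicated(coh$manifest$seed) > 0)
  expect_identical(coh$manifest$channel_id,
                   vapply(coh$recordings, function(r) r$channel_id, character(1)))
  expect_error(generate_cohort(tiny_cfg(n_prc = 1, n_nrc = 0)),
               class = "ecogmapr_config_error")
})

test_that("generated cohorts pass i/o round-trip and segmentation validation", {
  cfg <- tiny_cfg(n_prc = 1, n_nrc = 2)
  coh <- generate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(coh$recordings, path)
  back <- read_recording(path)
  expect_equal(back[[1]]$samples, coh$recordings[[1]]$samples, tolerance = 1e-12)
  for (rec in back) {
    bs <- extract_blocks(trim_to_task(rec), block_duration_s = 2)
    expect_identical(nrow(bs), 10L)
  }
})

test_that("the band-power effect scales with the configured gain", {
  ratios <- vapply(1:10, function(s) {
    rec <- generate_channel("PRC", tiny_cfg(effect_gain = 4), seed = 100 + s)
    bp <- band_power_summary(rec)
    mean(bp$power[bp$condition == "active"]) /
      mean(bp$power[bp$condition == "control"])
  }, numeric(1))
  expect_gt(mean(ratios), 2)

  null_ratios <- vapply(1:10, function(s) {
    rec <- generate_channel("PRC", tiny_cfg(effect_gain = 1), seed = 100 + s)
    bp <- band_power_summary(rec)
    mean(bp$power[bp$condition == "active"]) /
      mean(bp$power[bp$condition == "control"])
  }, numeric(1))
  expect_lt(abs(mean(null_ratios) - 1), 0.25)
})

test_that("negative channels show no active/control contrast", {
  ratios <- vapply(1:10, function(s) {
    rec <- generate_channel("NRC", tiny_cfg(effect_gain = 4), seed = 200 + s)
    bp <- band_power_summary(rec)
    mean(bp$power[bp$condition == "active"]) /
      mean(bp$power[bp$condition == "control"])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.25)
})

test_that("the conventional detector flags boosted channels in most seeds", {
  hits <- vapply(1:10, function(s) {
    rec <- generate_channel("PRC", tiny_cfg(effect_gain = 4), seed = 300 + s)
    conventional_detector(rec, band = c(70, 170))$detected == "PRC"
  }, logical(1))
  expect_gt(mean(hits), 0.5)
  false_hits <- vapply(1:10, function(s) {
    rec <- generate_channel("NRC", tiny_cfg(), seed = 400 + s)
    conventional_detector(rec, band = c(70, 170))$detected == "PRC"
  }, logical(1))
  expect_lt(mean(false_hits), 0.5)
})

test_that("power-neutral mode preserves total variance but shifts the spectrum", {
  cfg <- tiny_cfg(effect_gain = 6, power_neutral = TRUE, gain_jitter = 0,
                  baseline_jitter = 0)
  rec <- generate_channel("PRC", cfg, seed = 55)
  bs <- extract_blocks(trim_to_task(rec), block_duration_s = 2)
  v_act <- vapply(bs$samples[bs$condition == "active"], var, numeric(1))
  v_ctl <- vapply(bs$samples[bs$condition == "control"], var, numeric(1))
  expect_equal(mean(v_act) / mean(v_ctl), 1, tolerance = 0.1)
  bp <- band_power_summary(rec)
  expect_gt(mean(bp$power[bp$condition == "active"]) /
              mean(bp$power[bp$condition == "control"]), 2)
})

test_that("the spectral helpers behave on analytically known signals", {
  withr::local_seed(60)
  # white noise: flat spectrum, equal-width bands carry equal power
  x <- rnorm(20000)
  psd <- welch_psd(x, fs = 1000)
  b1 <- ecogmapr:::band_integral(psd, 100, 200)
  b2 <- ecogmapr:::band_integral(psd, 300, 400)
  expect_equal(b1 / b2, 1, tolerance = 0.15)
  expect_equal(ecogmapr:::band_integral(psd, 1, 499), var(x), tolerance = 0.05)
  # a pure 100 Hz tone lands in the 70-170 band
  tone <- sin(2 * pi * 100 * seq(0, 10, by = 1 / 600))
  rec <- ecog_recording("tone", tone[1:6000], 600,
                        annotations = tibble::tibble(
                          condition = "active", story_id = 1L,
                          start_sample = 0L, end_sample = 6000L))
  bp <- band_power_summary(rec, bands = list(low = c(1, 69),
                                             hg = c(70, 170),
                                             high = c(171, 299)))
  expect_gt(bp$power[bp$band == "hg"], 100 * max(bp$power[bp$band != "hg"]))
})

test_that("configuration validation names the failing constraint", {
  expect_error(synthetic_config(effect_band = c(70, 400), fs = 600),
               regexp = "effect_band", class = "ecogmapr_config_error")
  expect_error(synthetic_config(effect_gain = 0), class = "ecogmapr_config_error")
  expect_error(band_power_summary(generate_channel("NRC", tiny_cfg(), 1),
                                  bands = list(bad = c(100, 400))),
               class = "ecogmapr_validation_error")
})
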