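test_that("csv round-trip preserves samples, annotations, labels and order", {
  withr::local_seed(1)
  ann <- task_annotations(fs = 10, block_duration_s = 1, n_active = 5,
                          n_control = 5)
  recs <- lapply(c("gridA_01", "gridA_02", "gridB_07"), function(id) {
    ecog_recording(id, rnorm(100), fs = 10, annotations = ann,
                   truth_label = if (id == "gridA_02") "PRC" else "NRC")
  })
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(recs, path)
  back <- read_recording(path)

  expect_length(back, 3)
  expect_identical(vapply(back, function(r) r$channel_id, character(1)),
                   vapply(recs, function(r) r$channel_id, character(1)))
  for (i in 1:3) {
    expect_identical(back[[i]]$samples, recs[[i]]$samples)
    expect_equal(back[[i]]$annotations, recs[[i]]$annotations)
    expect_identical(back[[i]]$truth_label, recs[[i]]$truth_label)
    expect_identical(back[[i]]$fs, 10)
  }
})

test_that("a two-channel csv with sidecar yields one recording per channel", {
  dat <- tibble::tibble(ch1 = as.double(1:12), ch2 = as.double(12:1))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dat, path)
  jsonlite::write_json(list(fs = 1200), paste0(path, ".json"),
                       auto_unbox = TRUE)
  recs <- read_recording(path)
  expect_length(recs, 2)
  expect_identical(recs[[1]]$samples, as.double(1:12))
  expect_identical(recs[[2]]$samples, as.double(12:1))
  expect_identical(recs[[1]]$fs, 1200)
})

test_that("edf round-trip recovers fs exactly and samples within quantisation", {
  withr::local_seed(2)
  x1 <- rnorm(2400, sd = 40)
  x2 <- rnorm(2400, sd = 40)
  recs <- list(ecog_recording("c1", x1, 1200), ecog_recording("c2", x2, 1200))
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(recs, path)
  back <- read_recording(path)
  expect_identical(back[[1]]$fs, 1200)
  expect_identical(vapply(back, function(r) r$channel_id, character(1)),
                   c("c1", "c2"))
  # 16-bit quantisation: error bounded by one digital step
  step1 <- (max(x1) - min(x1)) / 65535
  expect_lt(max(abs(back[[1]]$samples - x1)), step1 * 1.01)
})

test_that("edf header fields parse against an independently constructed file", {
  # Build an EDF byte-by-byte per the published header layout: 1 channel,
  # 2 one-second records at 4 Hz, physical range -1..1, digital -32768..32767.
  path <- withr::local_tempfile(fileext = ".edf")
  con <- file(path, "wb")
  pad <- function(s, w) writeChar(formatC(s, width = w, flag = "-"), con,
                                  nchars = w, eos = NULL)
  pad("0", 8); pad("patient", 80); pad("recording", 80)
  pad("02.01.00", 8); pad("10.30.00", 8)
  pad("512", 8); pad("", 44); pad("2", 8); pad("1", 8); pad("1", 4)
  pad("chX", 16); pad("", 80); pad("uV", 8)
  pad("-1", 8); pad("1", 8); pad("-32768", 8); pad("32767", 8)
  pad("", 80); pad("4", 8); pad("", 32)
  digs <- as.integer(c(-32768, 0, 32767, 0, 16384, -16384, 0, 32767))
  writeBin(digs, con, size = 2L, endian = "little")
  close(con)

  recs <- read_recording(path, format = "edf")
  expect_length(recs, 1)
  expect_identical(recs[[1]]$channel_id, "chX")
  expect_identical(recs[[1]]$fs, 4)
  expect_length(recs[[1]]$samples, 8)
  # physical = -1 + (d + 32768) * 2/65535
  expect_equal(recs[[1]]$samples[1], -1)
  expect_equal(recs[[1]]$samples[3], 1)
  expect_equal(recs[[1]]$samples[2], -1 + 32768 * 2 / 65535, tolerance = 1e-12)
})

test_that("a cohort of 637 channels survives a round-trip intact", {
  withr::local_seed(3)
  recs <- lapply(seq_len(637), function(i) {
    ecog_recording(sprintf("e%03d", i), rnorm(8), fs = 1200)
  })
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(recs, path)
  back <- read_recording(path)
  expect_length(back, 637)
  expect_identical(back[[637]]$samples, recs[[637]]$samples)
})

test_that("i/o errors are specific", {
  expect_error(read_recording("no/such/file.csv"), class = "ecogmapr_io_error")
  # csv without sampling rate
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(a = 1:3), path)
  expect_error(read_recording(path), class = "ecogmapr_format_error")
  # overlapping annotations name the offending pair
  ann <- tibble::tibble(condition = c("control", "active"),
                        story_id = c(NA, 1L),
                        start_sample = c(0L, 5L), end_sample = c(10L, 15L))
  expect_error(ecog_recording("x", rnorm(20), 10, annotations = ann),
               regexp = "1 and 2 overlap", class = "ecogmapr_validation_error")
  # mixed sampling rates refuse to serialise
  expect_error(
    write_recording(list(ecog_recording("a", 1:4, 10),
                         ecog_recording("b", 1:4, 20)),
                    withr::local_tempfile(fileext = ".csv")),
    class = "ecogmapr_validation_error")
  expect_error(ecog_recording("x", 1:4, fs = -1),
               class = "ecogmapr_format_error")
})

test_that("empty and rich annotation sets round-trip through the sidecar", {
  rec_plain <- ecog_recording("solo", rnorm(30), 10)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_recording(list(rec_plain), p1)
  expect_identical(nrow(read_recording(p1)[[1]]$annotations), 0L)

  ann <- task_annotations(fs = 3, block_duration_s = 1, n_active = 5,
                          n_control = 5)
  rec <- ecog_recording("deca", rnorm(30), 3, annotations = ann,
                        truth_label = "NRC")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_recording(list(rec), p2)
  back <- read_recording(p2)[[1]]
  expect_equal(back$annotations, ann)
  expect_identical(back$truth_label, "NRC")
})
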