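# Minimal EDF (European Data Format) I/O: 16-bit integer data records with
# per-channel linear physical scaling.  Covers the subset of the format the
# package needs (equal-rate continuous channels); task annotations stay in the
# JSON sidecar, not in EDF events.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = -1)
  if (nchar(s) > width) s <- substr(formatC(x, format = "f", digits = width), 1, width)
  edf_pad(s, width)
}

write_edf <- function(recordings, path) {
  ns <- length(recordings)
  fs <- recordings[[1]]$fs
  lens <- vapply(recordings, function(r) length(r$samples), integer(1))
  if (length(unique(lens)) != 1L) {
    abort("EDF output needs equal-length channels.", class = "ecogmapr_validation_error")
  }
  n <- lens[1]
  if (n < 1) abort("EDF output needs non-empty channels.", class = "ecogmapr_validation_error")

  # 1-s records when the sample count divides evenly, else one whole-file record
  if (abs(fs - round(fs)) < 1e-9 && n %% round(fs) == 0) {
    nsamp <- as.integer(round(fs))
    n_rec <- n %/% nsamp
    rec_dur <- 1
  } else {
    nsamp <- n
    n_rec <- 1L
    rec_dur <- n / fs
  }

  phys_min <- phys_max <- numeric(ns)
  digs <- matrix(0L, nrow = n, ncol = ns)
  for (j in seq_len(ns)) {
    x <- recordings[[j]]$samples
    phys_min[j] <- min(x); phys_max[j] <- max(x)
    if (phys_max[j] <= phys_min[j]) phys_max[j] <- phys_min[j] + 1
    d <- round((x - phys_min[j]) / (phys_max[j] - phys_min[j]) * 65535 - 32768)
    digs[, j] <- as.integer(pmin(pmax(d, -32768), 32767))
  }

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_num(rec_dur, 8),
    edf_pad(ns, 4)
  )
  field <- function(f, width) {
    paste0(vapply(seq_len(ns), function(j) edf_pad(f(j), width), character(1)),
           collapse = "")
  }
  hdr <- paste0(
    hdr,
    field(function(j) recordings[[j]]$channel_id, 16),
    field(function(j) "", 80),
    field(function(j) recordings[[j]]$units, 8),
    field(function(j) edf_num(phys_min[j], 8), 8),
    field(function(j) edf_num(phys_max[j], 8), 8),
    field(function(j) "-32768", 8),
    field(function(j) "32767", 8),
    field(function(j) "", 80),
    field(function(j) nsamp, 8),
    field(function(j) "", 32)
  )
  writeBin(charToRaw(hdr), con)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * nsamp + 1L):(r * nsamp)
    for (j in seq_len(ns)) {
      writeBin(digs[idx, j], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd_str <- function(width) {
    trimws(rawToChar(readBin(con, "raw", width)))
  }
  rd_num <- function(width) as.numeric(rd_str(width))
  version <- rd_str(8)
  if (version != "0") {
    abort(sprintf("'%s' is not an EDF file (version field '%s').", path, version),
          class = "ecogmapr_format_error")
  }
  rd_str(80); rd_str(80); rd_str(8); rd_str(8)
  rd_num(8)                               # header bytes
  rd_str(44)
  n_rec <- rd_num(8)
  rec_dur <- rd_num(8)
  ns <- as.integer(rd_num(4))
  if (is.na(ns) || ns < 1) {
    abort(sprintf("EDF '%s': bad signal count.", path), class = "ecogmapr_format_error")
  }
  rd_fields <- function(width) vapply(seq_len(ns), function(j) rd_str(width), character(1))
  labels <- rd_fields(16)
  rd_fields(80)
  units <- rd_fields(8)
  pmin <- as.numeric(rd_fields(8))
  pmax <- as.numeric(rd_fields(8))
  dmin <- as.numeric(rd_fields(8))
  dmax <- as.numeric(rd_fields(8))
  rd_fields(80)
  nsamp <- as.integer(rd_fields(8))
  rd_fields(32)
  if (is.na(rec_dur) || rec_dur <= 0) {
    abort(sprintf("EDF '%s': record duration missing or non-positive.", path),
          class = "ecogmapr_format_error")
  }
  fs <- nsamp / rec_dur
  if (length(unique(fs)) != 1L) {
    abort(sprintf("EDF '%s': channels with mixed sampling rates are unsupported.", path),
          class = "ecogmapr_format_error")
  }
  store <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    rec <- readBin(con, "integer", n = sum(nsamp), size = 2L, signed = TRUE,
                   endian = "little")
    if (length(rec) < sum(nsamp)) {
      abort(sprintf("EDF '%s': truncated data record %d.", path, r),
            class = "ecogmapr_io_error")
    }
    store[[r]] <- rec
  }
  offsets <- cumsum(c(0L, nsamp))
  signals <- lapply(seq_len(ns), function(j) {
    d <- unlist(lapply(store, function(rec) rec[(offsets[j] + 1L):offsets[j + 1L]]),
                use.names = FALSE)
    pmin[j] + (d - dmin[j]) * (pmax[j] - pmin[j]) / (dmax[j] - dmin[j])
  })
  names(signals) <- make.unique(labels)
  list(fs = fs[1], signals = signals, units = units)
}
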