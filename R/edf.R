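# Minimal European Data Format (EDF) reader/writer: 16-bit samples, the
# standard 256-byte header plus 256 bytes per signal, fixed-length data
# records. Annotations (EDF+) are out of scope.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  edf_pad(s, width)
}

#' Write a multichannel recording to an EDF file
#'
#' Each channel is stored in its own signal with a one-second data record,
#' so per-channel sample rates must be positive integers. Samples are
#' linearly quantized to 16 bits over the channel's physical range.
#'
#' @param path output file path.
#' @param channels named list; each element a list with `data` (numeric
#'   vector) and `rate` (samples per second, integer).
#' @param start_time POSIXct recording start (defaults to a fixed epoch so
#'   that output is byte-reproducible).
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, channels,
                      start_time = as.POSIXct("2000-01-01 22:00:00", tz = "UTC")) {
  stopifnot(length(channels) >= 1, !is.null(names(channels)))
  rates <- vapply(channels, function(ch) ch$rate, numeric(1))
  if (any(rates != round(rates) | rates <= 0))
    stop("write_edf: channel rates must be positive integers (1 s records)")
  ns <- length(channels)
  n_rec <- min(floor(vapply(channels, function(ch) length(ch$data), numeric(1)) / rates))
  if (n_rec < 1) stop("write_edf: less than one second of data")

  con <- file(path, "wb")
  on.exit(close(con))

  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate X X X X", 80),
    edf_pad(format(start_time, "%d.%m.%y"), 8),
    edf_pad(format(start_time, "%H.%M.%S"), 8),
    edf_pad(256 * (ns + 1), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)

  phys_min <- numeric(ns); phys_max <- numeric(ns)
  for (i in seq_len(ns)) {
    d <- channels[[i]]$data
    lo <- min(d, na.rm = TRUE); hi <- max(d, na.rm = TRUE)
    if (!is.finite(lo) || !is.finite(hi)) { lo <- -1; hi <- 1 }
    if (hi - lo < 1e-9) { lo <- lo - 1; hi <- hi + 1 }
    phys_min[i] <- lo; phys_max[i] <- hi
  }

  field <- function(f) writeChar(paste0(vapply(seq_len(ns), f, character(1)),
                                        collapse = ""), con, eos = NULL)
  field(function(i) edf_pad(names(channels)[i], 16))
  field(function(i) edf_pad("", 80))
  field(function(i) edf_pad("", 8))
  field(function(i) edf_num(phys_min[i], 8))
  field(function(i) edf_num(phys_max[i], 8))
  field(function(i) edf_pad(-32768L, 8))
  field(function(i) edf_pad(32767L, 8))
  field(function(i) edf_pad("", 80))
  field(function(i) edf_pad(rates[i], 8))
  field(function(i) edf_pad("", 32))

  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    d <- channels[[i]]$data[seq_len(n_rec * rates[i])]
    scl <- (d - phys_min[i]) / (phys_max[i] - phys_min[i])
    dig[[i]] <- matrix(as.integer(round(scl * 65535 - 32768)), nrow = rates[i])
  }
  for (r in seq_len(n_rec))
    for (i in seq_len(ns))
      writeBin(dig[[i]][, r], con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return list with `duration_s`, `start_time`, and `channels`: a named
#'   list of `list(data, rate)` in physical units.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("read_edf: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (!identical(version, "0")) stop("read_edf: not a valid EDF file: ", path)
  rd(80); rd(80)
  d <- rd(8); tm <- rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec)) stop("read_edf: corrupt header")

  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (k in c(80, 8)) for (i in seq_len(ns)) rd(k)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)

  raw <- vector("list", ns)
  for (i in seq_len(ns)) raw[[i]] <- matrix(0L, nrow = spr[i], ncol = n_rec)
  for (r in seq_len(n_rec))
    for (i in seq_len(ns))
      raw[[i]][, r] <- readBin(con, "integer", n = spr[i], size = 2L,
                               signed = TRUE, endian = "little")

  channels <- vector("list", ns)
  for (i in seq_len(ns)) {
    g <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    channels[[i]] <- list(data = (as.vector(raw[[i]]) - dmin[i]) * g + pmin[i],
                          rate = spr[i] / rec_dur)
  }
  names(channels) <- labels
  start_time <- as.POSIXct(paste(d, tm), format = "%d.%m.%y %H.%M.%S", tz = "UTC")
  list(duration_s = n_rec * rec_dur, start_time = start_time, channels = channels)
}
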