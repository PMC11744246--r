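# Minimal European Data Format (EDF) writer/reader.
#
# No EDF package ships with this environment, so the subset of EDF needed
# here is implemented directly: fixed-width ASCII headers and 16-bit
# little-endian sample records with linear physical/digital scaling.
# Continuous recordings only; one-second data records.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write a multichannel recording to an EDF file
#'
#' @param path output file path
#' @param channels named list of numeric vectors (uV), equal lengths
#' @param fs sampling rate in Hz (integer samples per 1-s record)
#' @param start_time POSIXct recording start (default epoch origin)
#' @return `path`, invisibly
#' @export
write_edf <- function(path, channels, fs,
                      start_time = as.POSIXct("2000-01-01 22:00:00", tz = "UTC")) {
  stopifnot(is.list(channels), length(channels) >= 1, fs == round(fs))
  ns <- length(channels)
  n <- unique(lengths(channels))
  if (length(n) != 1) stop("all channels must have equal length")
  spr <- as.integer(fs)
  n_rec <- n %/% spr
  if (n_rec < 1) stop("recording shorter than one 1-s data record")
  n_use <- n_rec * spr

  dig_min <- -32768; dig_max <- 32767
  phys <- lapply(channels, function(x) {
    m <- max(abs(x[seq_len(n_use)]), 1e-6)
    c(-m, m)
  })

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate X X X X", 80),
    edf_pad(format(start_time, "%d.%m.%y"), 8),
    edf_pad(format(start_time, "%H.%M.%S"), 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(ns, 4)
  )
  field <- function(f, width) paste(vapply(seq_len(ns), f, ""), collapse = "")
  hdr <- paste0(
    hdr,
    field(function(i) edf_pad(names(channels)[i], 16), 16),
    field(function(i) edf_pad("", 80), 80),
    field(function(i) edf_pad("uV", 8), 8),
    field(function(i) edf_num(phys[[i]][1], 8), 8),
    field(function(i) edf_num(phys[[i]][2], 8), 8),
    field(function(i) edf_pad(dig_min, 8), 8),
    field(function(i) edf_pad(dig_max, 8), 8),
    field(function(i) edf_pad("", 80), 80),
    field(function(i) edf_pad(spr, 8), 8),
    field(function(i) edf_pad("", 32), 32)
  )
  writeChar(hdr, con, eos = NULL)

  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- channels[[i]][seq_len(n_use)]
    g <- (dig_max - dig_min) / (phys[[i]][2] - phys[[i]][1])
    d <- round((x - phys[[i]][1]) * g + dig_min)
    dig[[i]] <- matrix(as.integer(pmin(pmax(d, dig_min), dig_max)), nrow = spr)
  }
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      writeBin(dig[[i]][, r], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path
#' @return list with `channels` (named list of numeric vectors, physical
#'   units), `fs` (Hz), `start_time` (POSIXct)
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                       # version
  rd(80); rd(80)
  d <- rd(8); tm <- rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8) # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)

  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                 signed = TRUE, endian = "little")
  channels <- stats::setNames(vector("list", ns), labels)
  offs <- c(0L, cumsum(spr))
  rec_len <- sum(spr)
  for (i in seq_len(ns)) {
    idx <- as.vector(outer(seq_len(spr[i]) + offs[i],
                           (seq_len(n_rec) - 1L) * rec_len, `+`))
    g <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
    channels[[i]] <- (raw[idx] - dmin_[i]) * g + pmin_[i]
  }
  st <- as.POSIXct(paste(d, tm), format = "%d.%m.%y %H.%M.%S", tz = "UTC")
  list(channels = channels, fs = spr[1] / rec_dur, start_time = st)
}
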