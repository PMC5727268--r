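# Minimal EDF (European Data Format) reader/writer for two-channel
# EMG + trigger recordings. EDF stores 16-bit integers with a per-channel
# affine physical scaling; values are therefore quantized to one part in
# 65535 of the physical range. Data records are 1 s long and the final
# record is zero-padded, so recordings are padded to whole seconds.

.edf_pad <- function(s, width) {
  s <- substr(s, 1L, width)
  formatC(s, width = -width, flag = " ")
}

.edf_num <- function(x, width) .edf_pad(format(x, scientific = FALSE), width)

#' Write a recording as a two-signal EDF file
#'
#' Signals are labelled `EMG` (physical dimension uV) and `TRIG`. Samples
#' are quantized to the 16-bit digital range over the observed physical
#' range of each channel, and the recording is zero-padded to an integer
#' number of 1-second data records.
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "cmap_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n <- length(rec$emg)
  n_rec <- as.integer(ceiling(n / fs))
  pad <- n_rec * fs - n
  chans <- list(EMG = c(rec$emg, rep(0, pad)),
                TRIG = c(rec$trigger, rep(0, pad)))
  dims <- c("uV", "")

  phys_min <- phys_max <- dig <- vector("list", 2L)
  for (i in 1:2) {
    r <- range(chans[[i]])
    if (diff(r) == 0) r <- r + c(-1, 1)
    # widen 0.1% so extremes stay strictly inside the digital range,
    # then quantize against the header values exactly as written (the
    # 8-char ASCII fields truncate), so a round trip errs by <= LSB/2
    r <- r + diff(r) * c(-5e-4, 5e-4)
    r_str <- vapply(signif(r, 7), .edf_num, "", width = 8)
    r <- as.numeric(trimws(r_str))
    phys_min[[i]] <- r_str[1L]; phys_max[[i]] <- r_str[2L]
    scale <- (r[2L] - r[1L]) / 65535
    dig[[i]] <- as.integer(round((chans[[i]] - r[1L]) / scale) - 32768L)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  ns <- 2L
  header_bytes <- 256L + ns * 256L
  wr(.edf_pad("0", 8))                       # version
  wr(.edf_pad("X X X X", 80))                # patient id (anonymous)
  wr(.edf_pad("Startdate X X X X", 80))      # recording id
  wr(.edf_pad("01.01.00", 8))                # start date
  wr(.edf_pad("00.00.00", 8))                # start time
  wr(.edf_num(header_bytes, 8))
  wr(.edf_pad("", 44))                       # reserved
  wr(.edf_num(n_rec, 8))
  wr(.edf_num(1, 8))                         # record duration, seconds
  wr(.edf_num(ns, 4))
  labels <- names(chans)
  for (i in 1:2) wr(.edf_pad(labels[i], 16))
  for (i in 1:2) wr(.edf_pad("", 80))        # transducer
  for (i in 1:2) wr(.edf_pad(dims[i], 8))
  for (i in 1:2) wr(phys_min[[i]])
  for (i in 1:2) wr(phys_max[[i]])
  for (i in 1:2) wr(.edf_num(-32768, 8))
  for (i in 1:2) wr(.edf_num(32767, 8))
  for (i in 1:2) wr(.edf_pad("", 80))        # prefiltering
  for (i in 1:2) wr(.edf_num(fs, 8))         # samples per record
  for (i in 1:2) wr(.edf_pad("", 32))        # reserved

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in 1:2) writeBin(dig[[i]][idx], con, size = 2L,
                            endian = "little")
  }
  invisible(path)
}

#' Read a two-signal EDF file
#'
#' @param path Path to the EDF file.
#' @param emg_channel,trig_channel Channel labels to match
#'   (case-insensitive substring-free exact match after trimming).
#' @return A [recording()].
#' @export
read_edf <- function(path, emg_channel = "EMG", trig_channel = "TRIG") {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    trimws(readChar(con, width, useBytes = TRUE))
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header: ", path)
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)

  sig <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      sig[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        phys_min[i] + (d - dig_min[i]) * scale
    }
  }

  find_chan <- function(label) {
    hit <- which(toupper(labels) == toupper(label))
    if (length(hit) != 1L)
      stop("EDF channel '", label, "' not found (labels: ",
           paste(labels, collapse = ", "), ")")
    hit
  }
  if (ns != 2L && (toupper(emg_channel) == "EMG" &&
                   toupper(trig_channel) == "TRIG" &&
                   !all(c("EMG", "TRIG") %in% toupper(labels))))
    stop("EDF has ", ns, " channels; give an explicit channel mapping")
  ie <- find_chan(emg_channel)
  it <- find_chan(trig_channel)
  fs <- spr[ie] / rec_dur
  recording(sig[[ie]], sig[[it]], fs = fs,
            meta = list(source = path, edf_labels = labels))
}
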