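# Minimal European Data Format (EDF) I/O: fixed 1 s data records, 16-bit
# little-endian samples, physical units microvolts. Covers plain EDF only
# (EDF+ annotation signals are not written and are rejected on read).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Encodes samples as 16-bit integers in 1 s data records with a per-channel
#' symmetric physical range, so values round-trip to within one quantization
#' step of the channel's full-scale range. Channel labels are written as
#' `<lead_id><contact_index>` so the lead structure can be recovered on read.
#'
#' @param recording A `raw_recording`. The sampling rate must be an integer
#'   number of samples per second.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  fs <- recording$sampling_rate
  if (fs != round(fs))
    stop("EDF writer requires an integer sampling rate (samples per 1 s record)")
  fs <- as.integer(round(fs))
  s <- recording$samples
  nch <- nrow(s)
  n_rec <- ceiling(ncol(s) / fs)
  if (n_rec * fs > ncol(s)) {
    s <- cbind(s, matrix(0, nch, n_rec * fs - ncol(s)))
    message("EDF writer: padded recording with zeros to a whole data record")
  }

  phys_max <- pmax(apply(abs(s), 1L, max), 1e-6)
  dig_max <- 32767L
  labels <- paste0(recording$channels$lead_id,
                   recording$channels$contact_index)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L), edf_pad("X X X X", 80L), edf_pad("Startdate X X X X", 80L),
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),
    edf_pad(256L * (1L + nch), 8L), edf_pad("", 44L),
    edf_pad(n_rec, 8L), edf_pad(1L, 8L), edf_pad(nch, 4L))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(labels, 16L)
  field(rep("", nch), 80L)                       # transducer
  field(rep("uV", nch), 8L)                      # physical dimension
  field(sprintf("%.6g", -phys_max), 8L)          # physical minimum
  field(sprintf("%.6g", phys_max), 8L)           # physical maximum
  field(rep(-dig_max, nch), 8L)                  # digital minimum
  field(rep(dig_max, nch), 8L)                   # digital maximum
  field(rep("", nch), 80L)                       # prefiltering
  field(rep(fs, nch), 8L)                        # samples per record
  field(rep("", nch), 32L)

  scale <- dig_max / phys_max
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(nch)) {
      dig <- as.integer(round(s[ch, idx] * scale[ch]))
      dig <- pmin(pmax(dig, -dig_max), dig_max)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a recording from an EDF file
#'
#' Restores physical units from the per-channel digital-to-physical scaling
#' in the header and parses lead/contact metadata from the channel labels.
#'
#' @param path Path to an EDF file.
#' @param label_pattern Regular expression with two capture groups (lead id,
#'   contact index) applied to each channel label. Default matches labels of
#'   the form `LA1`, `RPI12`.
#' @return A `raw_recording`.
#' @export
read_edf <- function(path, label_pattern = "^([A-Za-z]+)([0-9]+)$") {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8L); rd(80L); rd(80L); rd(8L); rd(8L); rd(8L)
  reserved <- rd(44L)
  if (grepl("EDF\\+", reserved) && grepl("EDF\\+D", reserved))
    stop("discontinuous EDF+ files are not supported")
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  nch <- as.integer(rd(4L))
  if (is.na(n_rec) || is.na(nch) || nch < 1L)
    stop("not a parseable EDF header: ", path)
  rdv <- function(width) vapply(seq_len(nch), function(i) rd(width), "")
  labels <- rdv(16L); rdv(80L); rdv(8L)
  phys_min <- as.numeric(rdv(8L)); phys_max <- as.numeric(rdv(8L))
  dig_min <- as.numeric(rdv(8L)); dig_max <- as.numeric(rdv(8L))
  rdv(80L)
  spr <- as.integer(rdv(8L)); rdv(32L)

  if (any(labels == "EDF Annotations"))
    stop("EDF+ annotation signals are not supported")
  if (length(unique(spr)) != 1L)
    stop("mixed sampling rates across channels are not supported")
  fs <- spr[1L] / rec_dur
  m <- regmatches(labels, regexec(label_pattern, labels))
  bad <- which(vapply(m, length, 0L) != 3L)
  if (length(bad))
    stop("channel label(s) do not match the lead/contact pattern: ",
         paste(labels[bad], collapse = ", "))

  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  samples <- matrix(0, nch, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = nch * spr[1L], size = 2L,
                     signed = TRUE, endian = "little")
    idx <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    for (ch in seq_len(nch))
      samples[ch, idx] <-
        (block[((ch - 1L) * spr[1L] + 1L):(ch * spr[1L])] - dig_min[ch]) *
        scale[ch] + phys_min[ch]
  }
  channels <- data.frame(
    channel_id = labels,
    lead_id = vapply(m, `[`, "", 2L),
    contact_index = as.integer(vapply(m, `[`, "", 3L)),
    stringsAsFactors = FALSE)
  raw_recording(samples, fs, channels)
}
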