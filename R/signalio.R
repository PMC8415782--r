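#' Construct a raw multichannel recording
#'
#' Bundles a channels-by-time sample matrix (microvolts) with its sampling
#' rate and per-channel metadata. This is the common container for both
#' monopolar (contact-referenced) and bipolar-derived recordings.
#'
#' @param samples Numeric matrix, channels x time, in microvolts.
#' @param sampling_rate Sampling rate in Hz (scalar, > 0).
#' @param channels Data frame with one row per channel and columns
#'   `channel_id` (unique label), `lead_id` (electrode lead/grid name) and
#'   `contact_index` (integer position of the contact along its lead).
#'   An optional `anatomical_label` column is carried through untouched.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, sampling_rate, channels) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric channels x time matrix")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("`sampling_rate` must be a positive scalar (Hz)")
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  req <- c("channel_id", "lead_id", "contact_index")
  if (!all(req %in% names(channels)))
    stop("`channels` needs columns: ", paste(req, collapse = ", "))
  if (nrow(channels) != nrow(samples))
    stop("channel table has ", nrow(channels), " rows but `samples` has ",
         nrow(samples), " channels")
  if (anyDuplicated(channels$channel_id))
    stop("duplicate channel_id in channel table")
  dup <- duplicated(channels[, c("lead_id", "contact_index")])
  if (any(dup))
    stop("contact_index not unique within lead: ",
         paste(channels$channel_id[dup], collapse = ", "))
  rownames(samples) <- channels$channel_id
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channels = channels),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  dur <- ncol(x$samples) / x$sampling_rate
  cat(sprintf(
    "raw_recording: %d channels x %d samples (%.1f s @ %g Hz), %d lead(s)\n",
    nrow(x$samples), ncol(x$samples), dur, x$sampling_rate,
    length(unique(x$channels$lead_id))))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording A `raw_recording`.
#' @return Scalar duration in seconds.
#' @export
recording_duration <- function(recording) {
  ncol(recording$samples) / recording$sampling_rate
}

#' Construct and validate a cue event table
#'
#' @param onset_s,offset_s Numeric vectors of cue onsets/offsets in seconds.
#' @param label Character vector of class labels.
#' @return Data frame of class `event_table`, sorted by onset, with columns
#'   `onset_s`, `offset_s`, `label`.
#' @export
event_table <- function(onset_s, offset_s, label) {
  ev <- data.frame(onset_s = as.numeric(onset_s),
                   offset_s = as.numeric(offset_s),
                   label = as.character(label),
                   stringsAsFactors = FALSE)
  validate_events(ev)
}

validate_events <- function(ev) {
  if (nrow(ev) == 0L) {
    warning("event table is empty")
    class(ev) <- c("event_table", "data.frame")
    return(ev)
  }
  bad <- which(ev$offset_s <= ev$onset_s)
  if (length(bad))
    stop("event offset <= onset at row ", bad[1L])
  ord <- order(ev$onset_s)
  ev <- ev[ord, , drop = FALSE]
  rownames(ev) <- NULL
  if (nrow(ev) > 1L) {
    ovl <- which(ev$onset_s[-1L] < ev$offset_s[-nrow(ev)])
    if (length(ovl))
      stop("events overlap at row ", ovl[1L] + 1L)
  }
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Read a cue event table from a tab-separated file
#'
#' Expects a UTF-8 TSV with a header line `onset_s  offset_s  label` and
#' decimal seconds. Rows are validated (offsets after onsets, sorted, no
#' overlap) before being returned.
#'
#' @param path Path to the events TSV file.
#' @return An `event_table`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path)
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("numeric", "numeric", "character"))
  need <- c("onset_s", "offset_s", "label")
  if (!all(need %in% names(ev)))
    stop("events file must have header columns: ", paste(need, collapse = ", "))
  validate_events(ev[, need])
}

#' Write a cue event table as a tab-separated file
#' @param events An `event_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events)[, c("onset_s", "offset_s", "label")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a bipolar montage from adjacent contacts
#'
#' Pairs each contact with the next contact on the same lead (contact i minus
#' contact i + 1), the standard chain derivation that suppresses noise common
#' to neighboring contacts. A lead with k contiguous contacts yields k - 1
#' pairs; gaps in the contact numbering (explanted or dropped channels) are
#' never bridged, and single-contact leads contribute no pairs (warning).
#'
#' @param recording A `raw_recording` with monopolar channels.
#' @return Data frame of class `montage_spec` with columns `pair`
#'   (`"<lead>:<i>-<i+1>"`), `lead_id`, `minuend` and `subtrahend`
#'   (channel ids), ordered by lead then contact.
#' @export
build_bipolar_montage <- function(recording) {
  ch <- recording$channels
  out <- list()
  for (lead in unique(ch$lead_id)) {
    sub <- ch[ch$lead_id == lead, , drop = FALSE]
    sub <- sub[order(sub$contact_index), , drop = FALSE]
    if (nrow(sub) < 2L) {
      warning("lead ", lead, " has a single contact; no bipolar pairs")
      next
    }
    adj <- which(diff(sub$contact_index) == 1L)
    if (!length(adj)) next
    out[[lead]] <- data.frame(
      pair = sprintf("%s:%d-%d", lead, sub$contact_index[adj],
                     sub$contact_index[adj + 1L]),
      lead_id = lead,
      minuend = sub$channel_id[adj],
      subtrahend = sub$channel_id[adj + 1L],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no lead with >= 2 adjacent contacts")
  # stable order: leads in first-appearance order, contacts ascending
  mont <- do.call(rbind, out[unique(ch$lead_id)[unique(ch$lead_id) %in% names(out)]])
  rownames(mont) <- NULL
  class(mont) <- c("montage_spec", "data.frame")
  mont
}

#' Apply a bipolar montage to a recording
#'
#' Each output trace is the sample-wise difference minuend - subtrahend.
#'
#' @param recording A `raw_recording`.
#' @param montage A `montage_spec` from [build_bipolar_montage()].
#' @return A `raw_recording` whose channels are the bipolar pairs (the
#'   `channel_id` is the pair name).
#' @export
apply_montage <- function(recording, montage) {
  missing <- setdiff(unique(c(montage$minuend, montage$subtrahend)),
                     recording$channels$channel_id)
  if (length(missing))
    stop("montage references missing channel(s): ",
         paste(missing, collapse = ", "))
  s <- recording$samples
  bip <- s[montage$minuend, , drop = FALSE] -
    s[montage$subtrahend, , drop = FALSE]
  ch <- data.frame(channel_id = montage$pair,
                   lead_id = montage$lead_id,
                   contact_index = seq_len(nrow(montage)),
                   stringsAsFactors = FALSE)
  raw_recording(bip, recording$sampling_rate, ch)
}

#' Export a montage as a two-column TSV of channel ids
#' @param montage A `montage_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(montage, path) {
  utils::write.table(as.data.frame(montage)[, c("minuend", "subtrahend")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
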