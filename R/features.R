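#' Frequency band specification
#'
#' The default bands follow standard electrophysiology nomenclature with
#' three gamma bands of increasing width so integrated amplitudes stay
#' comparable as spectral power density falls with frequency:
#' delta_theta \[0, 10), alpha_mu \[10, 15), beta \[15, 30), gamma1
#' \[30, 100), gamma2 \[100, 500), gamma3 \[500, 5000) Hz. Intervals are
#' half-open so shared edges are never counted twice.
#'
#' @param name Character vector of band names.
#' @param low,high Numeric vectors of band edges in Hz; `low` inclusive,
#'   `high` exclusive.
#' @return Data frame of class `band_spec`, sorted by `low`.
#' @export
band_spec <- function(name = c("delta_theta", "alpha_mu", "beta",
                               "gamma1", "gamma2", "gamma3"),
                      low = c(0, 10, 15, 30, 100, 500),
                      high = c(10, 15, 30, 100, 500, 5000)) {
  b <- data.frame(name = as.character(name), low = as.numeric(low),
                  high = as.numeric(high), stringsAsFactors = FALSE)
  if (any(b$low >= b$high)) stop("band low must be < high")
  b <- b[order(b$low), , drop = FALSE]
  if (nrow(b) > 1L && any(b$high[-nrow(b)] > b$low[-1L] + 1e-12))
    stop("bands must be pairwise disjoint")
  rownames(b) <- NULL
  class(b) <- c("band_spec", "data.frame")
  b
}

#' Clip a band specification to a Nyquist frequency
#'
#' Bands entirely above Nyquist are dropped; a band straddling Nyquist is
#' truncated to end at Nyquist. Both adjustments emit a warning since they
#' change the feature set.
#'
#' @param bands A `band_spec`.
#' @param nyquist Nyquist frequency in Hz.
#' @return A `band_spec` valid for the given Nyquist.
#' @export
clip_bands <- function(bands, nyquist) {
  drop <- bands$low >= nyquist
  if (any(drop))
    warning("band(s) above Nyquist (", nyquist, " Hz) dropped: ",
            paste(bands$name[drop], collapse = ", "))
  bands <- bands[!drop, , drop = FALSE]
  trunc <- bands$high > nyquist
  if (any(trunc)) {
    warning("band(s) truncated at Nyquist (", nyquist, " Hz): ",
            paste(bands$name[trunc], collapse = ", "))
    bands$high[trunc] <- nyquist
  }
  if (!nrow(bands)) stop("no band remains below Nyquist")
  rownames(bands) <- NULL
  class(bands) <- c("band_spec", "data.frame")
  bands
}

#' Classic Blackman taper
#'
#' Symmetric Blackman window with the classic coefficients a0 = 0.42,
#' a1 = 0.5, a2 = 0.08, so the endpoints are exactly zero.
#'
#' @param n Number of coefficients (>= 2).
#' @return Numeric vector of length `n`.
#' @export
blackman_window <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("`n` must be an integer >= 2")
  k <- seq_len(n) - 1L
  0.42 - 0.5 * cos(2 * pi * k / (n - 1)) + 0.08 * cos(4 * pi * k / (n - 1))
}

#' Short-FFT amplitude spectrogram on non-overlapping windows
#'
#' Splits each channel into consecutive non-overlapping windows of
#' `window_s` seconds (a trailing partial window is discarded), applies the
#' Blackman taper and computes one-sided discrete Fourier amplitudes per
#' window. With the default 200 ms windows the bin spacing is 5 Hz.
#'
#' @param recording A `raw_recording` (typically bipolar).
#' @param window_s Window length in seconds; `window_s * sampling_rate`
#'   must be an integer.
#' @return List of class `window_spectra` with elements `amplitude`
#'   (array windows x bins x channels), `freqs` (Hz, from 0 to Nyquist,
#'   spacing `1/window_s`), `window_start_times` (s), `window_s`,
#'   `channel_id`, `sampling_rate`.
#' @export
window_spectra <- function(recording, window_s = 0.2) {
  fs <- recording$sampling_rate
  L <- window_s * fs
  if (abs(L - round(L)) > 1e-9)
    stop("window_s * sampling_rate must be an integer number of samples")
  L <- as.integer(round(L))
  n_win <- ncol(recording$samples) %/% L
  if (n_win < 1L) stop("recording shorter than one window")
  n_bins <- L %/% 2L + 1L
  taper <- blackman_window(L)
  nch <- nrow(recording$samples)
  amp <- array(0, dim = c(n_win, n_bins, nch))
  for (ch in seq_len(nch)) {
    seg <- matrix(recording$samples[ch, seq_len(n_win * L)], nrow = L)
    ft <- stats::mvfft(seg * taper)
    amp[, , ch] <- t(Mod(ft[seq_len(n_bins), , drop = FALSE]))
  }
  structure(list(
    amplitude = amp,
    freqs = (seq_len(n_bins) - 1L) / window_s,
    window_start_times = (seq_len(n_win) - 1L) * window_s,
    window_s = window_s,
    channel_id = recording$channels$channel_id,
    sampling_rate = fs), class = "window_spectra")
}

#' Integrate spectral amplitudes across frequency bands
#'
#' Sums amplitude bins with `low <= freq < high` per window, channel and
#' band ("integrated" read literally: when the bands partition the spectrum
#' the band sums conserve the total amplitude).
#'
#' @param spectra A `window_spectra`.
#' @param bands A `band_spec`; clipped to the spectrogram's Nyquist first.
#' @return List with `values` (windows x (channel x band) matrix), `features`
#'   (data frame: `pair`, `band`), `window_start_times`, `window_s`.
#' @export
integrate_bands <- function(spectra, bands = band_spec()) {
  bands <- clip_bands(bands, spectra$sampling_rate / 2)
  keep <- vapply(seq_len(nrow(bands)), function(i)
    any(spectra$freqs >= bands$low[i] & spectra$freqs < bands$high[i]),
    logical(1L))
  if (!all(keep)) {
    warning("band(s) containing no frequency bin dropped: ",
            paste(bands$name[!keep], collapse = ", "))
    bands <- bands[keep, , drop = FALSE]
  }
  nch <- length(spectra$channel_id)
  nb <- nrow(bands)
  n_win <- dim(spectra$amplitude)[1L]
  values <- matrix(0, n_win, nch * nb)
  feat <- data.frame(pair = rep(spectra$channel_id, each = nb),
                     band = rep(bands$name, nch),
                     stringsAsFactors = FALSE)
  for (ch in seq_len(nch)) {
    for (b in seq_len(nb)) {
      bins <- spectra$freqs >= bands$low[b] & spectra$freqs < bands$high[b]
      values[, (ch - 1L) * nb + b] <-
        rowSums(spectra$amplitude[, bins, ch, drop = FALSE])
    }
  }
  list(values = values, features = feat,
       window_start_times = spectra$window_start_times,
       window_s = spectra$window_s)
}

#' Centered boxcar smoothing of window series
#'
#' Moving average over `span_s` seconds (an odd number of windows, default
#' 1 s = 5 windows of 200 ms). Edges use shrinking windows: the mean of the
#' samples that fall inside the series.
#'
#' @param x Numeric vector or windows x features matrix.
#' @param span_s Smoothing span in seconds.
#' @param window_s Window step in seconds.
#' @param causal If `TRUE`, average over the trailing `span_s` instead of a
#'   centered span (real-time parity mode).
#' @return Smoothed object of the same shape.
#' @export
boxcar_smooth <- function(x, span_s = 1.0, window_s = 0.2, causal = FALSE) {
  span <- round(span_s / window_s)
  if (span <= 1L) return(x)
  if (!causal && span %% 2L == 0L)
    stop("centered boxcar span must be an odd number of windows; got ", span)
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1L) else x
  n <- nrow(m)
  cs <- rbind(0, apply(m, 2L, cumsum))
  half <- (span - 1L) %/% 2L
  lo <- if (causal) pmax(seq_len(n) - span + 1L, 1L) else pmax(seq_len(n) - half, 1L)
  hi <- if (causal) seq_len(n) else pmin(seq_len(n) + half, n)
  out <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  dimnames(out) <- dimnames(m)
  if (vec) out[, 1L] else out
}

#' Z-standardize feature series across the whole task
#'
#' Subtracts each feature's mean and divides by its standard deviation over
#' all windows. Features with zero variance are flagged and excluded (with a
#' warning), never silently zeroed. The constants are stored so the
#' transform can be inverted or applied to new windows.
#'
#' @param values Windows x features matrix.
#' @param features Data frame of feature metadata (one row per column).
#' @return List with standardized `values`, `features`, `center`, `scale`,
#'   and `excluded` (metadata rows of dropped features).
#' @keywords internal
standardize_values <- function(values, features) {
  center <- colMeans(values)
  scale <- apply(values, 2L, stats::sd)
  bad <- !is.finite(scale) | scale <= 0
  if (any(bad))
    warning(sum(bad), " zero-variance feature(s) excluded from IAF matrix")
  keep <- which(!bad)
  std <- scale(values[, keep, drop = FALSE],
               center = center[keep], scale = scale[keep])
  attr(std, "scaled:center") <- NULL
  attr(std, "scaled:scale") <- NULL
  list(values = std,
       features = features[keep, , drop = FALSE],
       center = center[keep], scale = scale[keep],
       excluded = features[bad, , drop = FALSE])
}

#' Extract integrated amplitude features (IAFs)
#'
#' Full feature pipeline: bipolar derivation (if a montage is supplied),
#' Blackman-tapered short FFT on a non-overlapping 200 ms window grid
#' anchored at the recording start, band integration, 1 s boxcar smoothing,
#' and z-standardization across the entire task. Deterministic and free of
#' randomness.
#'
#' @param recording A `raw_recording`.
#' @param montage Optional `montage_spec`; if supplied, applied first.
#' @param bands A `band_spec` (clipped to Nyquist automatically).
#' @param window_s Analysis window in seconds (default 0.2).
#' @param boxcar_s Boxcar span in seconds (default 1).
#' @param standardize Z-standardize across all windows (default `TRUE`).
#' @param causal_boxcar Use a trailing instead of centered boxcar.
#' @return Object of class `iaf_matrix`: `values` (windows x features),
#'   `features` (`pair`, `band`), `window_start_times`, `window_s`,
#'   `standardized`, `center`, `scale`, `excluded`.
#' @export
extract_iaf <- function(recording, montage = NULL, bands = band_spec(),
                        window_s = 0.2, boxcar_s = 1.0, standardize = TRUE,
                        causal_boxcar = FALSE) {
  if (!is.null(montage)) recording <- apply_montage(recording, montage)
  sp <- window_spectra(recording, window_s = window_s)
  ib <- integrate_bands(sp, bands)
  sm <- boxcar_smooth(ib$values, span_s = boxcar_s, window_s = window_s,
                      causal = causal_boxcar)
  out <- list(values = sm, features = ib$features,
              window_start_times = ib$window_start_times,
              window_s = window_s, standardized = FALSE,
              center = NULL, scale = NULL,
              excluded = ib$features[0, , drop = FALSE])
  if (standardize) {
    st <- standardize_values(sm, ib$features)
    out$values <- st$values
    out$features <- st$features
    out$center <- st$center
    out$scale <- st$scale
    out$excluded <- st$excluded
    out$standardized <- TRUE
  }
  colnames(out$values) <- paste(out$features$pair, out$features$band, sep = "|")
  class(out) <- "iaf_matrix"
  out
}

#' @export
print.iaf_matrix <- function(x, ...) {
  cat(sprintf("iaf_matrix: %d windows (%.1f s grid) x %d features%s\n",
              nrow(x$values), x$window_s, ncol(x$values),
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' Feature ids of an IAF matrix (`"<pair>|<band>"`)
#' @param iaf An `iaf_matrix`.
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(iaf) {
  paste(iaf$features$pair, iaf$features$band, sep = "|")
}

#' Write an IAF matrix as wide-format TSV plus a JSON metadata sidecar
#'
#' @param iaf An `iaf_matrix`.
#' @param path Output TSV path; metadata is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_iaf <- function(iaf, path) {
  df <- data.frame(window_start_s = iaf$window_start_times,
                   iaf$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(window_s = iaf$window_s, standardized = iaf$standardized,
               features = iaf$features, center = iaf$center,
               scale = iaf$scale, excluded = iaf$excluded)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an IAF matrix written by [write_iaf()]
#' @param path TSV path (with `<path>.json` sidecar present).
#' @return An `iaf_matrix`.
#' @export
read_iaf <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  out <- list(values = values,
              features = as.data.frame(meta$features),
              window_start_times = df$window_start_s,
              window_s = meta$window_s,
              standardized = isTRUE(meta$standardized),
              center = meta$center, scale = meta$scale,
              excluded = as.data.frame(meta$excluded))
  class(out) <- "iaf_matrix"
  out
}
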