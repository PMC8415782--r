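# Synthetic task-locked SEEG-like recordings with planted, ground-truthed
# band-limited amplitude modulations, so the feature-extraction, selection
# and decoding stages can be validated without patient data.

with_rng_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic recording generator
#'
#' Defaults emulate the cued sustained-movement task design: 4 s visual cues
#' followed by 4 s of rest, 16-contact depth leads, and evoked responses that
#' are phasic, phasic-tonic, or low-band suppressions riding on 1/f
#' background noise. The default 2 kHz sampling rate keeps simulations at
#' desk scale; bands above the resulting Nyquist are clipped automatically
#' downstream, mirroring reduced-rate operation of real acquisition systems.
#'
#' @param seed Integer RNG seed; identical configs give bit-identical output.
#' @param sampling_rate Sampling rate in Hz (default 2000).
#' @param n_leads Number of depth leads (default 2).
#' @param contacts_per_lead Contacts per lead (default 16).
#' @param classes Character vector of cue class names.
#' @param trials_per_class Cues per class (default 10).
#' @param cue_duration_s,rest_duration_s Cue/rest block lengths in seconds;
#'   must be positive multiples of 0.2 s so blocks align to the window grid.
#' @param informative_fraction Fraction of bipolar pairs carrying planted
#'   responses (default 0.2).
#' @param response_kinds Response shapes to cycle over informative pairs:
#'   subset of `"phasic_onset"`, `"phasic_onset_offset"`, `"phasic_tonic"`,
#'   `"low_band_suppression"`.
#' @param target_bands Candidate band names for planted modulations; by
#'   default gamma bands carry the excitatory kinds and the beta band
#'   carries suppressions (the canonical movement-related pattern of
#'   low-band desynchronization with gamma enhancement; beta is the
#'   narrowest default band wide enough for a carrier that stays clear of
#'   the neighboring integration bands at 5 Hz resolution).
#' @param effect_size Peak change of the planted integrated band amplitude,
#'   in SD units of the background band amplitude across windows (default 3).
#' @param amplitude_jitter_cv Coefficient of variation of the per-trial
#'   response amplitude (default 0.2).
#' @param latency_jitter_s SD of the per-trial onset latency shift (default 0.05).
#' @param background List: `exponent` (power-spectral 1/f^b exponent, default
#'   2), `scale_uv` (background SD in microvolts, default 10),
#'   `white_fraction` (relative SD of added broadband white noise, default 0.02).
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         sampling_rate = 2000,
                         n_leads = 2L,
                         contacts_per_lead = 16L,
                         classes = c("open", "close"),
                         trials_per_class = 10L,
                         cue_duration_s = 4.0,
                         rest_duration_s = 4.0,
                         informative_fraction = 0.2,
                         response_kinds = c("phasic_onset",
                                            "phasic_onset_offset",
                                            "phasic_tonic",
                                            "low_band_suppression"),
                         target_bands = NULL,
                         effect_size = 3,
                         amplitude_jitter_cv = 0.2,
                         latency_jitter_s = 0.05,
                         background = list()) {
  bg <- utils::modifyList(
    list(exponent = 2, scale_uv = 10, white_fraction = 0.02), background)
  cfg <- list(seed = as.integer(seed), sampling_rate = sampling_rate,
              n_leads = as.integer(n_leads),
              contacts_per_lead = as.integer(contacts_per_lead),
              classes = as.character(classes),
              trials_per_class = as.integer(trials_per_class),
              cue_duration_s = cue_duration_s,
              rest_duration_s = rest_duration_s,
              informative_fraction = informative_fraction,
              response_kinds = match.arg(response_kinds,
                                         several.ok = TRUE),
              target_bands = target_bands,
              effect_size = effect_size,
              amplitude_jitter_cv = amplitude_jitter_cv,
              latency_jitter_s = latency_jitter_s,
              background = bg)
  if (length(cfg$classes) < 1L) stop("at least one cue class is required")
  if (cfg$trials_per_class < 1L) stop("trials_per_class must be >= 1")
  if (cfg$n_leads < 1L || cfg$contacts_per_lead < 2L)
    stop("need >= 1 lead with >= 2 contacts")
  for (fld in c("cue_duration_s", "rest_duration_s")) {
    v <- cfg[[fld]]
    if (v <= 0 || abs(v / 0.2 - round(v / 0.2)) > 1e-9)
      stop(fld, " must be a positive multiple of 0.2 s")
  }
  if (cfg$informative_fraction < 0 || cfg$informative_fraction >= 1)
    stop("informative_fraction must be in [0, 1)")
  class(cfg) <- "synth_config"
  cfg
}

#' Evoked-response envelope templates
#'
#' Unit-normalized envelopes over epoch time, relative to cue onset. Phasic
#' kinds are transient bumps that decay well before the cue offset;
#' `phasic_onset_offset` adds a second bump after the cue offset;
#' `phasic_tonic` holds a sustained plateau (>= 0.5 of peak) through the
#' cue; `low_band_suppression` is a non-positive plateau emulating
#' movement-related desynchronization of ongoing low-band rhythms.
#'
#' @param kind One of `"phasic_onset"`, `"phasic_onset_offset"`,
#'   `"phasic_tonic"`, `"low_band_suppression"`.
#' @param epoch_times Numeric vector of times in seconds relative to cue
#'   onset (may extend past the cue offset).
#' @param cue_duration_s Cue length in seconds.
#' @return Numeric envelope in \[-1, 1\] over `epoch_times`; zero before
#'   cue onset.
#' @export
make_response_envelope <- function(kind, epoch_times, cue_duration_s = 4.0) {
  d <- cue_duration_s
  t <- epoch_times
  bump <- function(mu, sig = 0.3) exp(-0.5 * ((t - mu) / sig)^2)
  ramp <- function(mu, sig) stats::plogis((t - mu) / sig)
  env <- switch(
    kind,
    phasic_onset = bump(0.4),
    phasic_onset_offset = pmin(bump(0.4) + bump(d + 0.4), 1),
    phasic_tonic = pmax(bump(0.4),
                        0.6 * ramp(0.2, 0.08) * (1 - ramp(d + 0.2, 0.12))),
    low_band_suppression = -ramp(0.3, 0.1) * (1 - ramp(d + 0.2, 0.15)),
    stop("unknown response kind: ", kind))
  env[t < 0] <- 0
  env
}

band_amp_series <- function(x, fs, window_s, low, high) {
  L <- as.integer(round(window_s * fs))
  n_win <- length(x) %/% L
  seg <- matrix(x[seq_len(n_win * L)], nrow = L)
  ft <- stats::mvfft(seg * blackman_window(L))
  freqs <- (seq_len(L %/% 2L + 1L) - 1L) / window_s
  bins <- which(freqs >= low & freqs < high)
  colSums(Mod(ft[bins, , drop = FALSE]))
}

one_over_f_noise <- function(n, exponent) {
  # spectral shaping of white gaussian noise: power ~ f^(-exponent)
  white <- stats::rnorm(n)
  ft <- stats::fft(white)
  freqs <- c(1e-12, seq_len(n - 1L))         # cycle counts; DC suppressed
  freqs <- pmin(freqs, n - freqs)            # fold to two-sided
  ft <- ft * freqs^(-exponent / 2)
  ft[1L] <- 0
  x <- Re(stats::fft(ft, inverse = TRUE)) / n
  x / stats::sd(x)
}

band_carrier <- function(n, fs, low, high, inset_hz = 5) {
  # carrier edges are inset by one spectral bin where the band is wide
  # enough, so filter roll-off does not plant repeatable energy in the
  # adjacent integration bands
  nyq <- fs / 2
  lo <- if (low > 0 && high - low >= 2 * inset_hz) low + inset_hz else low
  hi <- if (high < nyq && high - low >= 2 * inset_hz) high - inset_hz else
    min(high, nyq * 0.98)
  x <- stats::rnorm(n)
  filt <- if (lo <= 0) {
    signal::butter(4, hi / nyq, type = "low")
  } else if (hi >= nyq * 0.98 && high >= nyq) {
    signal::butter(4, lo / nyq, type = "high")
  } else {
    signal::butter(2, c(lo, hi) / nyq, type = "pass")
  }
  y <- signal::filtfilt(filt, x)
  y / stats::sd(y)
}

#' Simulate a task-locked multichannel recording
#'
#' Generates 1/f background noise at every contact, schedules cue/rest
#' blocks in randomized class order, and plants band-limited carrier-noise
#' modulations at a subset of bipolar pairs. Each informative pair's carrier
#' is injected as a common-mode signal into the contiguous run of contacts
#' from the lead tip through the pair's first contact — a spatially extended
#' source with an amplitude step between the pair's two contacts — so chain
#' bipolar subtraction cancels it everywhere except the target pair.
#' Carrier amplitude is calibrated so the planted peak changes the pair's
#' integrated band amplitude by `effect_size` background SDs.
#'
#' @param config A [synth_config()].
#' @return List with `recording` (`raw_recording`), `events`
#'   (`event_table`), and `truth` (ground truth: data frame
#'   `informative_features` with pair, band, kind, class, effect_size, plus
#'   the event schedule).
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$sampling_rate
  nyq <- fs / 2
  with_rng_seed(config$seed, {
    # --- event schedule: randomized class order, lead-in rest block
    n_trials <- length(config$classes) * config$trials_per_class
    order_lab <- sample(rep(config$classes, config$trials_per_class))
    block <- config$cue_duration_s + config$rest_duration_s
    onsets <- config$rest_duration_s + (seq_len(n_trials) - 1L) * block
    events <- event_table(onsets, onsets + config$cue_duration_s, order_lab)
    total_s <- config$rest_duration_s + n_trials * block
    n_samp <- as.integer(round(total_s * fs))

    # --- channel table and montage geometry
    leads <- paste0("L", LETTERS[seq_len(config$n_leads)])
    channels <- data.frame(
      channel_id = paste0(rep(leads, each = config$contacts_per_lead),
                          rep(seq_len(config$contacts_per_lead),
                              config$n_leads)),
      lead_id = rep(leads, each = config$contacts_per_lead),
      contact_index = rep(seq_len(config$contacts_per_lead), config$n_leads),
      stringsAsFactors = FALSE)
    pairs <- data.frame(
      lead = rep(leads, each = config$contacts_per_lead - 1L),
      i = rep(seq_len(config$contacts_per_lead - 1L), config$n_leads),
      stringsAsFactors = FALSE)
    pairs$pair <- sprintf("%s:%d-%d", pairs$lead, pairs$i, pairs$i + 1L)

    # --- pick informative pairs, kinds, bands, classes
    n_inf <- round(config$informative_fraction * nrow(pairs))
    bands <- clip_bands_quiet(band_spec(), nyq)
    exc_bands <- intersect(
      config$target_bands %||% c("gamma1", "gamma2"), bands$name)
    sup_bands <- intersect(
      config$target_bands %||% "beta", bands$name)
    if (!length(exc_bands)) exc_bands <- utils::tail(bands$name, 1L)
    if (!length(sup_bands)) sup_bands <- bands$name[1L]
    truth_rows <- NULL
    if (n_inf > 0L) {
      inf_idx <- sample(nrow(pairs), n_inf)
      kinds <- rep_len(config$response_kinds, n_inf)
      band_of <- character(n_inf)
      band_of[kinds == "low_band_suppression"] <-
        rep_len(sup_bands, sum(kinds == "low_band_suppression"))
      band_of[kinds != "low_band_suppression"] <-
        rep_len(exc_bands, sum(kinds != "low_band_suppression"))
      truth_rows <- data.frame(
        pair = pairs$pair[inf_idx], lead = pairs$lead[inf_idx],
        contact = pairs$i[inf_idx], kind = kinds, band = band_of,
        class = rep_len(config$classes, n_inf),
        effect_size = config$effect_size, stringsAsFactors = FALSE)
    }

    # --- 1/f background per contact
    nch <- nrow(channels)
    samples <- matrix(0, nch, n_samp)
    for (ch in seq_len(nch)) {
      x <- one_over_f_noise(n_samp, config$background$exponent)
      if (config$background$white_fraction > 0)
        x <- x + config$background$white_fraction * stats::rnorm(n_samp)
      samples[ch, ] <- config$background$scale_uv * x
    }

    # --- plant responses
    tt <- (seq_len(n_samp) - 1L) / fs
    if (!is.null(truth_rows) && config$effect_size > 0) {
      for (r in seq_len(nrow(truth_rows))) {
        info <- truth_rows[r, ]
        b <- bands[bands$name == info$band, ]
        lead_rows <- which(channels$lead_id == info$lead)
        minu <- lead_rows[info$contact]
        subt <- lead_rows[info$contact + 1L]
        # background band-amplitude stats of this pair's bipolar trace
        bg_bip <- samples[minu, ] - samples[subt, ]
        amp_bg <- band_amp_series(bg_bip, fs, 0.2, b$low, b$high)
        mu_a <- mean(amp_bg); sd_a <- stats::sd(amp_bg)

        carrier <- band_carrier(n_samp, fs, b$low, b$high)
        kappa <- mean(band_amp_series(carrier, fs, 0.2, b$low, b$high))
        rho <- sqrt((mu_a + config$effect_size * sd_a)^2 - mu_a^2) / kappa

        env <- numeric(n_samp)
        ev_cls <- events[events$label == info$class, , drop = FALSE]
        for (k in seq_len(nrow(ev_cls))) {
          lat <- stats::rnorm(1L, 0, config$latency_jitter_s)
          amp <- max(0, stats::rnorm(1L, 1, config$amplitude_jitter_cv))
          span <- which(tt >= ev_cls$onset_s[k] - 0.5 &
                          tt < ev_cls$onset_s[k] + block)
          env[span] <- env[span] + amp * make_response_envelope(
            info$kind, tt[span] - ev_cls$onset_s[k] - lat,
            config$cue_duration_s)
        }
        planted <- if (info$kind == "low_band_suppression") {
          rho * pmax(0, 1 + env) * carrier
        } else {
          rho * pmax(0, env) * carrier
        }
        prefix <- lead_rows[seq_len(info$contact)]
        samples[prefix, ] <- sweep(samples[prefix, , drop = FALSE], 2L,
                                   planted, `+`)
      }
    }

    recording <- raw_recording(samples, fs, channels)
    truth <- list(
      informative_features = truth_rows %||%
        data.frame(pair = character(), lead = character(),
                   contact = integer(), kind = character(),
                   band = character(), class = character(),
                   effect_size = numeric(), stringsAsFactors = FALSE),
      events = as.data.frame(events))
    list(recording = recording, events = events, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clip_bands_quiet <- function(bands, nyquist)
  suppressWarnings(clip_bands(bands, nyquist))

#' Write simulation ground truth as a JSON sidecar
#' @param truth Ground-truth list from [simulate_recording()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#' @param path JSON path.
#' @return Ground-truth list.
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
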