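test_that("blackman taper has the classic closed-form values", {
  for (n in c(5L, 64L, 2001L)) {
    w <- blackman_window(n)
    expect_equal(w[1L], 0.42 - 0.5 + 0.08)
    expect_equal(w[n], 0)
    expect_equal(w, rev(w))               # symmetry
  }
  expect_equal(blackman_window(2001L)[1001L], 1.0)  # odd n midpoint
  expect_error(blackman_window(1L), ">= 2")
})

test_that("window spectra have the stated bin spacing and locate tones", {
  # 200 ms windows give 5 Hz bins regardless of sampling rate
  for (fs in c(500, 2000, 10000)) {
    rec <- raw_recording(matrix(rnorm(fs), 1L), fs,
                         data.frame(channel_id = "LA1", lead_id = "LA",
                                    contact_index = 1L))
    sp <- window_spectra(rec, window_s = 0.2)
    expect_equal(diff(sp$freqs)[1L], 5)
    expect_equal(length(sp$window_start_times), 5L)
  }

  # pure 100 Hz tone peaks at the 100 Hz bin in every window
  fs <- 2000
  tone <- sin(2 * pi * 100 * seq(0, 2, by = 1 / fs))[-1L]
  rec <- raw_recording(matrix(tone, 1L), fs,
                       data.frame(channel_id = "LA1", lead_id = "LA",
                                  contact_index = 1L))
  sp <- window_spectra(rec)
  peak_bins <- apply(sp$amplitude[, , 1L], 1L, which.max)
  expect_true(all(sp$freqs[peak_bins] == 100))

  expect_error(window_spectra(raw_recording(
    matrix(rnorm(10), 1L), 2000,
    data.frame(channel_id = "LA1", lead_id = "LA", contact_index = 1L))),
    "shorter")
})

test_that("windowed amplitudes match a brute-force DFT oracle", {
  set.seed(31)
  fs <- 250; L <- 50L
  x <- rnorm(3L * L)          # exactly 3 windows
  rec <- raw_recording(matrix(x, 1L), fs,
                       data.frame(channel_id = "LA1", lead_id = "LA",
                                  contact_index = 1L))
  sp <- window_spectra(rec, window_s = 0.2)
  taper <- blackman_window(L)
  for (w in 1:3) {
    oracle <- dft_amplitude_oracle(x[((w - 1L) * L + 1L):(w * L)], taper)
    expect_lt(max(abs(sp$amplitude[w, , 1L] - oracle)) /
                max(oracle), 1e-9)
  }
})

test_that("band integration follows the half-open convention and conserves", {
  # hand-built flat spectrum: every bin amplitude 1
  sp <- structure(list(
    amplitude = array(1, dim = c(4L, 26L, 1L)),
    freqs = seq(0, 125, by = 5),
    window_start_times = (0:3) * 0.2, window_s = 0.2,
    channel_id = "LA:1-2", sampling_rate = 250), class = "window_spectra")
  ib <- suppressWarnings(integrate_bands(sp, band_spec()))
  dt <- ib$values[, ib$features$band == "delta_theta"]
  expect_equal(unname(dt), rep(2, 4))      # bins {0, 5} only

  # partition of [0, Nyquist) conserves the total amplitude below Nyquist
  total_bands <- rowSums(ib$values)
  total_bins <- rowSums(sp$amplitude[, sp$freqs < 125, 1L, drop = FALSE])
  expect_equal(unname(total_bands), unname(total_bins))
})

test_that("a gamma-band burst raises gamma1 above beta during the burst", {
  set.seed(8)
  fs <- 500
  n <- 6L * fs
  x <- rnorm(n, sd = 0.2)
  burst <- (2L * fs + 1L):(4L * fs)
  bf <- signal::butter(2, c(35, 95) / (fs / 2), type = "pass")
  x[burst] <- x[burst] + 5 * signal::filtfilt(bf, rnorm(length(burst)))
  rec <- raw_recording(matrix(x, 1L), fs,
                       data.frame(channel_id = "LA1", lead_id = "LA",
                                  contact_index = 1L))
  ib <- suppressWarnings(integrate_bands(window_spectra(rec)))
  g1 <- ib$values[, ib$features$band == "gamma1"]
  be <- ib$values[, ib$features$band == "beta"]
  in_burst <- ib$window_start_times >= 2 & ib$window_start_times < 4
  expect_true(all(g1[in_burst] > be[in_burst]))
})

test_that("boxcar smoothing equals a brute-force sliding mean", {
  expect_equal(boxcar_smooth(rep(3.5, 20)), rep(3.5, 20))  # constants

  imp <- numeric(21); imp[10L] <- 1
  sm <- boxcar_smooth(imp, span_s = 1, window_s = 0.2)
  expect_equal(sm[8:12], rep(0.2, 5))
  expect_equal(sum(sm[-(8:12)]), 0)

  set.seed(4)
  x <- rnorm(57)
  sm <- boxcar_smooth(x, span_s = 1, window_s = 0.2)
  oracle <- vapply(seq_along(x), function(i)
    mean(x[max(1, i - 2):min(length(x), i + 2)]), 0)
  expect_equal(sm, oracle)

  # causal variant averages the trailing span only
  smc <- boxcar_smooth(x, span_s = 1, window_s = 0.2, causal = TRUE)
  oracle_c <- vapply(seq_along(x), function(i)
    mean(x[max(1, i - 4):i]), 0)
  expect_equal(smc, oracle_c)

  expect_equal(boxcar_smooth(x, span_s = 0.1, window_s = 0.2), x)  # identity
  expect_error(boxcar_smooth(x, span_s = 0.8, window_s = 0.2), "odd")
})

test_that("standardization is exact, invertible, and flags constants", {
  set.seed(9)
  vals <- cbind(rnorm(50, 10, 3), rnorm(50, -2, 0.5), rep(7, 50))
  feats <- data.frame(pair = "LA:1-2", band = c("beta", "gamma1", "gamma2"))
  expect_warning(st <- seegdecode:::standardize_values(vals, feats),
                 "zero-variance")
  expect_equal(ncol(st$values), 2L)
  expect_equal(st$excluded$band, "gamma2")
  expect_lt(max(abs(colMeans(st$values))), 1e-9)
  expect_lt(max(abs(apply(st$values, 2L, sd) - 1)), 1e-9)
  # inverse transform restores the original values
  back <- sweep(sweep(st$values, 2L, st$scale, `*`), 2L, st$center, `+`)
  expect_lt(max(abs(back - vals[, 1:2])), 1e-12)
})

test_that("IAF extraction yields pairs x bands features and is pure", {
  rec <- make_test_recording(n_leads = 3L, contacts = 16L, fs = 2000,
                             dur_s = 3, seed = 3L)
  iaf1 <- suppressWarnings(extract_iaf(rec, build_bipolar_montage(rec)))
  # 45 bipolar pairs x 6 bands (gamma3 truncated at Nyquist, not dropped)
  expect_equal(ncol(iaf1$values), 45L * 6L)
  expect_equal(nrow(iaf1$values), 15L)     # floor(3 s / 0.2 s)
  iaf2 <- suppressWarnings(extract_iaf(rec, build_bipolar_montage(rec)))
  expect_identical(iaf1$values, iaf2$values)
})

test_that("IAF matrices round-trip through TSV persistence", {
  sim <- planted_sim()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_iaf(sim$iaf, tmp)
  back <- read_iaf(tmp)
  expect_equal(unname(back$values), unname(sim$iaf$values), tolerance = 1e-8)
  expect_equal(back$features$band, sim$iaf$features$band)
  expect_true(back$standardized)
})

test_that("band specs reject overlap and clip at Nyquist", {
  expect_error(band_spec(c("a", "b"), c(0, 5), c(10, 20)), "disjoint")
  expect_error(band_spec("a", 10, 10), "low must be <")
  expect_warning(expect_warning(cb <- clip_bands(band_spec(), 250),
                                "dropped"), "truncated")
  expect_equal(cb$high[cb$name == "gamma2"], 250)
  expect_false("gamma3" %in% cb$name)
})
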