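# Shared fixtures, built in code. Simulations that several tests reuse are
# cached per session so the suite stays fast.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# small monopolar recording with known lead structure
make_test_recording <- function(n_leads = 1L, contacts = 4L, fs = 250,
                                dur_s = 2, seed = 42L) {
  set.seed(seed)
  leads <- paste0("L", LETTERS[seq_len(n_leads)])
  nch <- n_leads * contacts
  channels <- data.frame(
    channel_id = paste0(rep(leads, each = contacts),
                        rep(seq_len(contacts), n_leads)),
    lead_id = rep(leads, each = contacts),
    contact_index = rep(seq_len(contacts), n_leads))
  raw_recording(matrix(rnorm(nch * fs * dur_s), nch), fs, channels)
}

# standard small planted simulation reused across repeatability tests
planted_sim <- function() {
  cached("planted_sim", {
    cfg <- synth_config(seed = 11L, sampling_rate = 500, n_leads = 2L,
                        contacts_per_lead = 8L, classes = c("A", "B"),
                        trials_per_class = 10L, effect_size = 4,
                        amplitude_jitter_cv = 0.2)
    sim <- suppressWarnings(simulate_recording(cfg))
    iaf <- suppressWarnings(
      extract_iaf(sim$recording, build_bipolar_montage(sim$recording)))
    list(sim = sim, iaf = iaf,
         truth_ids = paste(sim$truth$informative_features$pair,
                           sim$truth$informative_features$band, sep = "|"))
  })
}

# brute-force single-sided DFT amplitude oracle: direct summed exponentials
dft_amplitude_oracle <- function(x, taper) {
  n <- length(x)
  xt <- x * taper
  vapply(0:(n %/% 2), function(k) {
    Mod(sum(xt * exp(-2i * pi * k * (0:(n - 1)) / n)))
  }, numeric(1))
}

# brute-force Pearson r from the covariance/variance definition
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
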