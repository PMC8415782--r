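test_that("event tables validate intervals and report offending rows", {
  ev <- event_table(c(0, 10, 20), c(4, 14, 24), c("a", "b", "a"))
  expect_s3_class(ev, "event_table")
  expect_equal(nrow(ev), 3L)

  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, tmp)
  back <- read_events(tmp)
  expect_equal(back$onset_s, ev$onset_s)
  expect_equal(back$label, ev$label)

  # inverted interval at row 3 is named
  bad <- data.frame(onset_s = c(0, 10, 22), offset_s = c(4, 14, 20),
                    label = "a")
  write.table(bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_events(tmp), "row 3")

  # overlap detection
  expect_error(event_table(c(0, 3), c(4, 7), c("a", "b")), "overlap")

  # empty body: empty table plus warning
  writeLines("onset_s\toffset_s\tlabel", tmp)
  expect_warning(empty <- read_events(tmp), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("bipolar montage pairs adjacent contacts within leads only", {
  rec <- make_test_recording(n_leads = 1L, contacts = 16L)
  m <- build_bipolar_montage(rec)
  expect_equal(nrow(m), 15L)
  expect_equal(m$pair[1L], "LA:1-2")

  rec3 <- make_test_recording(n_leads = 3L, contacts = 16L)
  expect_equal(nrow(build_bipolar_montage(rec3)), 45L)

  # a gap in contact numbering is not bridged
  ch <- data.frame(channel_id = c("LA1", "LA2", "LA4", "LA5"),
                   lead_id = "LA", contact_index = c(1L, 2L, 4L, 5L))
  rec_gap <- raw_recording(matrix(rnorm(4 * 100), 4), 100, ch)
  mg <- build_bipolar_montage(rec_gap)
  expect_equal(mg$pair, c("LA:1-2", "LA:4-5"))

  # single-contact lead warns and contributes nothing
  ch1 <- rbind(ch, data.frame(channel_id = "LB1", lead_id = "LB",
                              contact_index = 1L))
  rec1 <- raw_recording(matrix(rnorm(5 * 100), 5), 100, ch1)
  expect_warning(m1 <- build_bipolar_montage(rec1), "single contact")
  expect_equal(nrow(m1), 2L)
})

test_that("montage application subtracts sample-wise and is linear", {
  fs <- 200
  tvec <- seq(0, 1, length.out = fs)
  ch <- data.frame(channel_id = c("LA1", "LA2", "LA3"), lead_id = "LA",
                   contact_index = 1:3)
  s <- rbind(sin(2 * pi * 5 * tvec), 0 * tvec, sin(2 * pi * 5 * tvec))
  rec <- raw_recording(s, fs, ch)
  m <- build_bipolar_montage(rec)
  bip <- apply_montage(rec, m)
  expect_equal(bip$samples["LA:1-2", ], sin(2 * pi * 5 * tvec))
  # identical signals cancel exactly
  expect_equal(max(abs(bip$samples["LA:2-3", ] + bip$samples["LA:1-2", ] -
                         (s[1, ] - s[3, ]))), 0)

  # random pair equals element-wise subtraction oracle
  rec_r <- make_test_recording(n_leads = 2L, contacts = 5L, seed = 7L)
  mr <- build_bipolar_montage(rec_r)
  bipr <- apply_montage(rec_r, mr)
  for (i in seq_len(nrow(mr)))
    expect_equal(bipr$samples[i, ],
                 unname(rec_r$samples[mr$minuend[i], ] -
                          rec_r$samples[mr$subtrahend[i], ]))

  # linearity: montage(a x + b y) = a montage(x) + b montage(y)
  recx <- make_test_recording(seed = 1L); recy <- make_test_recording(seed = 2L)
  mm <- build_bipolar_montage(recx)
  mix <- recx; mix$samples <- 2 * recx$samples - 3 * recy$samples
  lhs <- apply_montage(mix, mm)$samples
  rhs <- 2 * apply_montage(recx, mm)$samples -
    3 * apply_montage(recy, mm)$samples
  expect_equal(lhs, rhs)

  # missing channel rejected
  m_bad <- mm; m_bad$minuend[1L] <- "ZZ9"
  expect_error(apply_montage(recx, m_bad), "ZZ9")
})

test_that("EDF round trip preserves samples to 16-bit quantization", {
  rec <- make_test_recording(n_leads = 1L, contacts = 16L, fs = 200,
                             dur_s = 3)
  tmp <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, tmp)
  back <- read_edf(tmp)
  expect_equal(back$sampling_rate, 200)
  expect_equal(back$channels$lead_id, rep("LA", 16L))
  expect_equal(back$channels$contact_index, 1:16)
  qstep <- max(abs(rec$samples)) / 32767
  expect_lt(max(abs(back$samples - rec$samples)), 1.01 * qstep)
})

test_that("EDF reader rejects labels that do not match the pattern", {
  rec <- make_test_recording()
  tmp <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, tmp)
  expect_error(read_edf(tmp, label_pattern = "^(XX)([0-9]+)$"), "LA1")
})

test_that("EDF output is readable by an independent reader (mne)", {
  rec <- make_test_recording(n_leads = 1L, contacts = 4L, fs = 100,
                             dur_s = 2)
  tmp <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, tmp)
  out <- withr::local_tempfile(fileext = ".tsv")
  script <- sprintf(paste0(
    "import mne, numpy as np\n",
    "raw = mne.io.read_raw_edf(%s, preload=True, verbose='ERROR')\n",
    "np.savetxt(%s, raw.get_data() * 1e6, delimiter='\\t')\n"),
    deparse(tmp), deparse(out))
  py <- withr::local_tempfile(fileext = ".py")
  writeLines(script, py)
  status <- system2("python", py, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out) && file.size(out) > 0)
  got <- as.matrix(read.table(out, sep = "\t"))
  qstep <- max(abs(rec$samples)) / 32767
  expect_lt(max(abs(got - unname(rec$samples))), 1.01 * qstep)
})
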