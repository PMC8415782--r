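# helper: build an iaf_matrix directly from a values matrix
iaf_from_matrix <- function(values, window_s = 0.2) {
  nf <- ncol(values)
  structure(list(
    values = values,
    features = data.frame(pair = paste0("LA:", seq_len(nf), "-",
                                        seq_len(nf) + 1L),
                          band = "beta"),
    window_start_times = (seq_len(nrow(values)) - 1L) * window_s,
    window_s = window_s, standardized = FALSE,
    center = NULL, scale = NULL,
    excluded = data.frame(pair = character(), band = character())),
    class = "iaf_matrix")
}

test_that("epochs snap to the window grid and span cue + 400 ms", {
  iaf <- iaf_from_matrix(matrix(seq_len(800), 400, 2))  # 80 s of windows
  ev <- event_table(c(10.0, 30.0), c(14.0, 34.0), c("m", "m"))
  ep <- epoch_features(iaf, ev)
  expect_equal(dim(ep$epochs$m), c(2L, 22L, 2L))        # 4.4 s / 0.2 s
  expect_equal(ep$rel_times$m[22L], 4.2)
  # epoch covers [10.0, 14.4): first window is the one starting at 10.0
  expect_equal(ep$epochs$m[1L, 1L, 1L], iaf$values[51L, 1L])

  # off-grid onset snaps back to the last grid start
  ev2 <- event_table(10.05, 14.05, "m")
  ep2 <- epoch_features(iaf, ev2)
  expect_equal(ep2$epochs$m[1L, 1L, 1L], iaf$values[51L, 1L])

  # ten events of one class give ten trials
  ev10 <- event_table(seq(0, 72, by = 8), seq(4, 76, by = 8), rep("m", 10))
  expect_equal(dim(epoch_features(iaf, ev10)$epochs$m)[1L], 10L)

  # trial extending past the recording end is dropped with a warning
  ev_off <- event_table(c(0, 78.6), c(4, 82.6), c("m", "m"))
  expect_warning(ep_off <- epoch_features(iaf, ev_off), "dropped")
  expect_equal(dim(ep_off$epochs$m)[1L], 1L)

  # unequal durations within a class rejected unless cropping requested
  ev_mix <- event_table(c(0, 10), c(4, 13), c("m", "m"))
  expect_error(epoch_features(iaf, ev_mix), "unequal")
  expect_silent(epoch_features(iaf, ev_mix, crop_to_min = TRUE))
})

test_that("composite response is the per-element trial mean", {
  iaf <- iaf_from_matrix(matrix(rnorm(600), 200, 3))  # 40 s of windows
  ev <- event_table(seq(0, 32, 8), seq(4, 36, 8), rep("m", 5))
  ep <- epoch_features(iaf, ev)
  comp <- composite_response(ep)
  # brute-force per-element mean over the 5 trials
  oracle <- apply(ep$epochs$m, c(2L, 3L), function(v) sum(v) / length(v))
  expect_equal(comp$composite$m, oracle)

  # single trial: composite equals the trial
  ep1 <- epoch_features(iaf, event_table(0, 4, "m"))
  expect_equal(composite_response(ep1)$composite$m,
               ep1$epochs$m[1L, , ])

  # antisymmetric pair averages to zero
  ep2 <- ep
  ep2$epochs$m <- ep$epochs$m[1:2, , , drop = FALSE]
  ep2$epochs$m[2L, , ] <- -ep2$epochs$m[1L, , ]
  expect_equal(max(abs(composite_response(ep2)$composite$m)), 0)
})

test_that("mcc equals a brute-force Pearson-then-average loop", {
  set.seed(17)
  n_tr <- 8L; n_w <- 22L; n_f <- 3L
  arr <- array(rnorm(n_tr * n_w * n_f), c(n_tr, n_w, n_f))
  ep <- structure(list(
    epochs = list(m = arr), rel_times = list(m = (0:21) * 0.2),
    features = data.frame(pair = paste0("P", 1:n_f), band = "beta"),
    window_s = 0.2, trial_map = list(m = 1:n_tr)), class = "epoch_set")

  tab <- mcc(ep, mode = "include_all")
  tab_loo <- mcc(ep, mode = "leave_one_out")
  for (f in seq_len(n_f)) {
    comp <- colMeans(arr[, , f])
    rs <- vapply(seq_len(n_tr), function(tr)
      pearson_oracle(arr[tr, , f], comp), 0)
    expect_lt(abs(tab$mcc[f] - mean(rs)), 1e-12)
    rs_loo <- vapply(seq_len(n_tr), function(tr)
      pearson_oracle(arr[tr, , f], colMeans(arr[-tr, , f])), 0)
    expect_lt(abs(tab_loo$mcc[f] - mean(rs_loo)), 1e-12)
  }
})

test_that("mcc handles identical and degenerate trials as defined", {
  base <- sin(seq(0, 3, length.out = 22L))
  arr <- array(0, c(4L, 22L, 2L))
  for (tr in 1:4) arr[tr, , 1L] <- base        # identical, non-constant
  arr[1L, , 2L] <- base; arr[2L, , 2L] <- -base  # composite = 0
  arr[3:4, , 2L] <- 5                           # constant trials
  ep <- structure(list(
    epochs = list(m = arr), rel_times = list(m = (0:21) * 0.2),
    features = data.frame(pair = c("P1", "P2"), band = "beta"),
    window_s = 0.2, trial_map = list(m = 1:4)), class = "epoch_set")
  tab <- mcc(ep)
  expect_equal(tab$mcc[tab$pair == "P1"], 1.0)
  # P2: constant trials excluded; remaining two cancel to a zero-variance
  # composite, so no valid trial remains
  expect_false(tab$valid[tab$pair == "P2"])
})

test_that("mcc is invariant to trial order and positive affine transforms", {
  set.seed(23)
  arr <- array(rnorm(5L * 12L * 2L), c(5L, 12L, 2L))
  make_ep <- function(a) structure(list(
    epochs = list(m = a), rel_times = list(m = (0:11) * 0.2),
    features = data.frame(pair = c("P1", "P2"), band = "beta"),
    window_s = 0.2, trial_map = list(m = seq_len(dim(a)[1L]))),
    class = "epoch_set")
  t1 <- mcc(make_ep(arr))
  t2 <- mcc(make_ep(arr[c(3, 1, 5, 2, 4), , , drop = FALSE]))
  expect_equal(t1$mcc, t2$mcc)
  t3 <- mcc(make_ep(arr * 3.7 + 11))
  expect_equal(t1$mcc, t3$mcc, tolerance = 1e-12)
})

test_that("selection rules apply strictly and monotonically", {
  tab <- structure(data.frame(
    class = "m", feature = c("A", "B", "C"), pair = c("A", "B", "C"),
    band = "beta", mcc = c(0.7, 0.6, 0.5), n_valid_trials = 5L,
    valid = TRUE), class = c("mcc_table", "data.frame"))
  expect_equal(select_features(tab, ">0.6")$selected, "A")   # strict
  expect_setequal(select_features(tab, ">-1")$selected, c("A", "B", "C"))
  expect_setequal(select_features(tab, "0.4:0.6")$selected, c("B", "C"))

  # invalid features are never selected
  tab$valid[1L] <- FALSE
  expect_warning(sel <- select_features(tab, ">0.65"))
  expect_length(sel$selected, 0L)

  # monotone: raising the threshold never enlarges the selection
  set.seed(5)
  rt <- structure(data.frame(
    class = rep(c("a", "b"), each = 50L),
    feature = rep(sprintf("F%02d", 1:50), 2L),
    pair = "P", band = "beta", mcc = runif(100, -1, 1),
    n_valid_trials = 5L, valid = TRUE),
    class = c("mcc_table", "data.frame"))
  thresholds <- seq(-1, 1, by = 0.2)
  sizes <- vapply(thresholds, function(th) length(
    suppressWarnings(select_features(rt, sprintf(">%f", th)))$selected), 0L)
  expect_true(all(diff(sizes) <= 0L))

  # union over classes
  rt2 <- rt; rt2$mcc <- c(rep(0.9, 2), rep(0, 48), rep(0, 48), rep(0.9, 2))
  sel2 <- select_features(rt2, ">0.6")
  expect_setequal(sel2$selected, c("F01", "F02", "F49", "F50"))
  expect_setequal(sel2$per_class$a, c("F01", "F02"))
})

test_that("leave-one-out mcc is less optimistic than include-all on noise", {
  set.seed(71)
  n_f <- 200L
  arr <- array(rnorm(8L * 12L * n_f), c(8L, 12L, n_f))
  ep <- structure(list(
    epochs = list(m = arr), rel_times = list(m = (0:11) * 0.2),
    features = data.frame(pair = sprintf("P%03d", seq_len(n_f)),
                          band = "beta"),
    window_s = 0.2, trial_map = list(m = 1:8)), class = "epoch_set")
  inc <- mcc(ep, "include_all")$mcc
  loo <- mcc(ep, "leave_one_out")$mcc
  expect_lt(t.test(loo, inc, paired = TRUE, alternative = "less")$p.value,
            0.01)
})
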