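#' Label IAF windows from the event table
#'
#' Assigns each window on the IAF grid the class of the cue covering it
#' (from the cue onset, snapped to the window grid, through 400 ms past the
#' cue offset — the same extension used for epoching); all other windows
#' are rest (class 0). Rest is an explicit decoding class: decoders must
#' predict through rest periods too.
#'
#' @param events An `event_table`.
#' @param window_start_times Window-grid start times (s) of the IAF matrix.
#' @param post_offset_s Label extension past the cue offset (default 0.4).
#' @param window_s Window step (default 0.2).
#' @return List of class `window_labels`: `labels` (integer per window,
#'   0 = rest), `classes` (names of classes 1..K), `window_start_times`.
#' @export
make_window_labels <- function(events, window_start_times,
                               post_offset_s = 0.4, window_s = 0.2) {
  n_win <- length(window_start_times)
  classes <- sort(unique(events$label))
  labels <- integer(n_win)
  claimed <- integer(n_win)
  for (i in seq_len(nrow(events))) {
    start <- floor(events$onset_s[i] / window_s + 1e-9) + 1L
    n_ep <- as.integer(round(
      (events$offset_s[i] - events$onset_s[i] + post_offset_s) / window_s))
    idx <- start:min(start + n_ep - 1L, n_win)
    if (any(claimed[idx] != 0L))
      stop("labeled intervals overlap at event row ", i,
           " (cue extension runs into the next cue)")
    claimed[idx] <- i
    labels[idx] <- match(events$label[i], classes)
  }
  structure(list(labels = labels, classes = classes,
                 window_start_times = window_start_times),
            class = "window_labels")
}

#' Split IAF windows into contiguous train and test partitions
#'
#' Splits at a trial boundary: the first `round(train_fraction * n_trials)`
#' cues (with their surrounding rest) form the training block, the rest the
#' independent test block, so no window of any trial appears in both
#' partitions. Rejects splits that leave any cue class absent from either
#' partition.
#'
#' @param iaf An `iaf_matrix`.
#' @param labels A `window_labels` on the same grid.
#' @param events The `event_table`.
#' @param train_fraction Fraction of trials used for training (default 0.75).
#' @return List with `train` and `test`, each holding `x` (windows x
#'   features), `y` (integer labels), `idx` (window indices), plus
#'   `train_events` and `test_events`.
#' @export
split_train_test <- function(iaf, labels, events, train_fraction = 0.75) {
  n_tr <- nrow(events)
  n_train <- round(train_fraction * n_tr)
  if (n_train < 1L || n_train >= n_tr)
    stop("train_fraction leaves an empty partition")
  tr_ev <- events[seq_len(n_train), , drop = FALSE]
  te_ev <- events[(n_train + 1L):n_tr, , drop = FALSE]
  missing_tr <- setdiff(labels$classes, tr_ev$label)
  if (length(missing_tr))
    stop("class absent from train partition: ",
         paste(missing_tr, collapse = ", "))
  missing_te <- setdiff(labels$classes, te_ev$label)
  if (length(missing_te))
    stop("class absent from test partition: ",
         paste(missing_te, collapse = ", "))
  boundary <- floor(te_ev$onset_s[1L] / iaf$window_s + 1e-9)  # windows before first test cue
  idx_tr <- seq_len(boundary)
  idx_te <- (boundary + 1L):nrow(iaf$values)
  list(train = list(x = iaf$values[idx_tr, , drop = FALSE],
                    y = labels$labels[idx_tr], idx = idx_tr),
       test = list(x = iaf$values[idx_te, , drop = FALSE],
                   y = labels$labels[idx_te], idx = idx_te),
       train_events = validate_events(as.data.frame(tr_ev)),
       test_events = validate_events(as.data.frame(te_ev)),
       classes = labels$classes, window_s = iaf$window_s)
}

subset_features <- function(x, feature_names, selection) {
  if (is.null(selection)) return(x)
  sel <- if (inherits(selection, "feature_selection")) selection$selected
  else as.character(selection)
  if (!length(sel))
    stop("empty feature selection: relax the MCC rule before training")
  keep <- feature_names %in% sel
  if (!any(keep)) stop("no IAF feature matches the selection")
  x[, keep, drop = FALSE]
}

#' Train a gaussian-kernel multi-class SVM window decoder
#'
#' One-vs-one multi-class SVM with an RBF (gaussian) kernel over per-window
#' IAF vectors (memoryless by design: its contrast with the LSTM's temporal
#' memory is the point of the architecture comparison). `gamma` and `cost`
#' are chosen by a small grid search with contiguous (blocked) k-fold
#' cross-validation on the training windows, respecting the time structure.
#'
#' @param x Training windows x features matrix.
#' @param y Integer labels per window (0 = rest).
#' @param gamma,cost Either scalars (used as-is) or vectors defining the
#'   tuning grid. Defaults: `gamma = c(0.5, 1, 2)/ncol(x)`,
#'   `cost = c(1, 10)`.
#' @param folds Blocked CV folds for tuning (default 3).
#' @param seed RNG seed (kept for interface symmetry; libsvm training is
#'   deterministic).
#' @return Object of class `svm_decoder`.
#' @export
train_svm <- function(x, y, gamma = NULL, cost = NULL, folds = 3L,
                      seed = 1L) {
  if (length(unique(y)) < 2L)
    stop("SVM training needs >= 2 classes present")
  if (ncol(x) < 1L)
    stop("SVM training needs >= 1 feature")
  gammas <- gamma %||% (c(0.5, 1, 2) / ncol(x))
  costs <- cost %||% c(1, 10)
  if (length(gammas) > 1L || length(costs) > 1L) {
    grid <- expand.grid(gamma = gammas, cost = costs)
    fold_id <- cut(seq_along(y), folds, labels = FALSE)
    acc <- numeric(nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      correct <- 0L
      for (fd in seq_len(folds)) {
        ho <- fold_id == fd
        if (length(unique(y[!ho])) < 2L) next
        fit <- e1071::svm(x[!ho, , drop = FALSE], factor(y[!ho]),
                          kernel = "radial", gamma = grid$gamma[gi],
                          cost = grid$cost[gi], scale = FALSE)
        pred <- stats::predict(fit, x[ho, , drop = FALSE])
        correct <- correct + sum(as.integer(as.character(pred)) == y[ho])
      }
      acc[gi] <- correct
    }
    best <- which.max(acc)
    gammas <- grid$gamma[best]; costs <- grid$cost[best]
  }
  fit <- e1071::svm(x, factor(y), kernel = "radial", gamma = gammas,
                    cost = costs, scale = FALSE)
  structure(list(fit = fit, gamma = gammas, cost = costs),
            class = "svm_decoder")
}

#' @export
predict.svm_decoder <- function(object, x, ...) {
  as.integer(as.character(stats::predict(object$fit, x)))
}

#' Cut a window stream into equal-length training chunks
#'
#' @param x Windows x features matrix.
#' @param y Integer labels per window.
#' @param chunk_len Chunk length in windows; a trailing partial chunk is
#'   dropped.
#' @param stride Step between chunk starts (default `chunk_len`, i.e.
#'   non-overlapping; a smaller stride yields overlapping training chunks).
#' @return List with `X` (features x time x chunks) and `Y` (time x chunks,
#'   values `y + 1` so rest becomes class 1).
#' @export
make_chunks <- function(x, y, chunk_len, stride = chunk_len) {
  starts <- seq(1L, nrow(x) - chunk_len + 1L, by = stride)
  if (!length(starts)) stop("fewer windows than one chunk")
  X <- array(0, dim = c(ncol(x), chunk_len, length(starts)))
  Y <- matrix(0L, chunk_len, length(starts))
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + chunk_len - 1L)
    X[, , k] <- t(x[idx, , drop = FALSE])
    Y[, k] <- y[idx] + 1L
  }
  list(X = X, Y = Y)
}

#' Train an LSTM window decoder on a window stream
#'
#' Slices the contiguous training windows into equal-length chunks (default
#' one cue + rest block) and fits [lstm_fit()]. The number of output
#' classes is `max(label) + 1` (rest plus cue classes).
#'
#' @param x Training windows x features matrix.
#' @param y Integer labels per window (0 = rest).
#' @param n_classes Total classes including rest.
#' @param chunk_len Sequence chunk length in windows (default 40, one
#'   4 s cue + 4 s rest block on the 200 ms grid).
#' @param align Number of leading windows to drop before chunking so chunk
#'   boundaries coincide with trial (cue + rest block) boundaries. Chunk
#'   alignment matters: chunks that cut a cue in half present cue-labeled
#'   windows with no preceding onset evidence, which destabilizes training.
#'   [evaluate_decoder()] computes this offset from the event schedule.
#' @param stride Chunk stride in windows (default `chunk_len`,
#'   non-overlapping).
#' @param val_fraction Fraction of training chunks held out to monitor
#'   early stopping. Default 0: with small synthetic sessions a tiny
#'   validation split is dominated by single-trial amplitude variability,
#'   so the monitored quantity defaults to training loss and model capacity
#'   is controlled by `l2` instead.
#' @param hidden,epochs,lr,patience,restarts,l2 Passed to [lstm_fit()].
#' @param seed RNG seed (initialization and validation split).
#' @return Object of class `lstm_decoder`.
#' @export
train_lstm <- function(x, y, n_classes = max(y) + 1L, chunk_len = 40L,
                       align = 0L, stride = chunk_len,
                       val_fraction = 0,
                       hidden = 32L, epochs = 200L, lr = 0.02,
                       patience = 200L, restarts = 3L, l2 = 1e-3,
                       seed = 1L) {
  if (length(unique(y)) < 2L)
    stop("LSTM training needs >= 2 classes present")
  if (ncol(x) < 1L)
    stop("LSTM training needs >= 1 feature")
  if (align > 0L) {
    x <- x[-seq_len(align), , drop = FALSE]
    y <- y[-seq_len(align)]
  }
  ch <- make_chunks(x, y, chunk_len, stride)
  model <- lstm_fit(ch$X, ch$Y, n_classes = n_classes, hidden = hidden,
                    epochs = epochs, lr = lr, patience = patience,
                    restarts = restarts, l2 = l2, seed = seed,
                    val_fraction = val_fraction)
  structure(list(model = model, chunk_len = chunk_len), class = "lstm_decoder")
}

#' @export
predict.lstm_decoder <- function(object, x, ...) {
  # run the stream in chunk_len segments with a state reset between them,
  # matching the sequence length distribution seen in training; the
  # trailing partial segment is run as its own short sequence
  n <- nrow(x)
  cl <- object$chunk_len
  pred <- integer(n)
  start <- 1L
  while (start <= n) {
    end <- min(start + cl - 1L, n)
    pred[start:end] <- predict(object$model,
                               t(x[start:end, , drop = FALSE]))
    start <- end + 1L
  }
  pred - 1L
}

#' Train and evaluate a decoder with repeated re-trainings
#'
#' Re-trains the decoder `n_repeats` times with different seeds on the same
#' contiguous split and reports window-wise test accuracy as mean +/- SD
#' (the repeat-to-repeat variability of training), a confusion matrix
#' summed over repeats, the chance level (frequency of the majority test
#' label), and trial-wise majority-vote accuracy over cue epochs.
#'
#' @param split Output of [split_train_test()].
#' @param kind `"svm"` or `"lstm"`.
#' @param feature_names Feature ids for the columns of the split matrices.
#' @param selection Optional `feature_selection` (or character vector of
#'   feature ids); `NULL` uses all features.
#' @param config Named list of decoder arguments (see [train_svm()] /
#'   [train_lstm()]).
#' @param n_repeats Number of re-trainings (default 5; SD needs >= 2).
#' @param seed Base seed; repeat r uses `seed + r`.
#' @return Object of class `eval_report`.
#' @export
evaluate_decoder <- function(split, kind = c("svm", "lstm"),
                             feature_names, selection = NULL,
                             config = list(), n_repeats = 5L, seed = 1L) {
  kind <- match.arg(kind)
  xtr <- subset_features(split$train$x, feature_names, selection)
  xte <- subset_features(split$test$x, feature_names, selection)
  ytr <- split$train$y; yte <- split$test$y
  n_classes <- length(split$classes) + 1L
  if (kind == "lstm") {
    # chunk on the trial grid: one cue+rest block per chunk, aligned so
    # chunk boundaries fall on cue onsets
    ws <- split$window_s %||% 0.2
    onsets <- split$train_events$onset_s
    if (is.null(config$chunk_len))
      config$chunk_len <- if (length(onsets) > 1L)
        as.integer(round(stats::median(diff(onsets)) / ws)) else 40L
    if (is.null(config$align))
      config$align <- as.integer(floor(onsets[1L] / ws + 1e-9) %%
                                   config$chunk_len)
  }
  accs <- numeric(n_repeats)
  conf <- matrix(0L, n_classes, n_classes,
                 dimnames = list(true = c("rest", split$classes),
                                 predicted = c("rest", split$classes)))
  preds_last <- NULL
  for (r in seq_len(n_repeats)) {
    dec <- if (kind == "svm") {
      do.call(train_svm, c(list(x = xtr, y = ytr, seed = seed + r), config))
    } else {
      do.call(train_lstm, c(list(x = xtr, y = ytr, n_classes = n_classes,
                                 seed = seed + r), config))
    }
    pred <- predict(dec, xte)
    accs[r] <- mean(pred == yte)
    conf <- conf + table(factor(yte, levels = 0:(n_classes - 1L)),
                         factor(pred, levels = 0:(n_classes - 1L)))
    preds_last <- pred
  }
  chance <- max(table(yte)) / length(yte)
  structure(list(
    accuracy = accs, mean = mean(accs),
    sd = if (n_repeats >= 2L) stats::sd(accs) else NA_real_,
    confusion = conf, chance = chance,
    n_features = ncol(xtr), decoder = kind,
    selection = if (is.null(selection)) "none"
    else paste(format_rule(selection), collapse = ""),
    n_repeats = n_repeats, predictions = preds_last,
    test_y = yte, test_idx = split$test$idx),
    class = "eval_report")
}

format_rule <- function(selection) {
  if (!inherits(selection, "feature_selection")) return("custom")
  r <- selection$rule
  if (!is.null(r$threshold)) sprintf(">%g", r$threshold)
  else sprintf("%g:%g", r$range[1L], r$range[2L])
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report [%s, selection %s]: accuracy %.2f%% +/- %s (chance %.2f%%, %d features, %d repeats)\n",
    x$decoder, x$selection, 100 * x$mean,
    if (is.na(x$sd)) "NA" else sprintf("%.2f%%", 100 * x$sd),
    100 * x$chance, x$n_features, x$n_repeats))
  invisible(x)
}

#' Run the four decoding architectures on one recording
#'
#' Evaluates SVM and LSTM decoders, each with and without MCC-based feature
#' selection, on the same contiguous train/test split with the same repeat
#' seeds. Feature selection is computed from training trials only, so no
#' test window influences the selected set.
#'
#' @param iaf An `iaf_matrix`.
#' @param events The `event_table`.
#' @param rule MCC selection rule (default `">0.6"`).
#' @param svm_config,lstm_config Decoder argument lists.
#' @param train_fraction Contiguous train fraction (default 0.75).
#' @param n_repeats Re-trainings per architecture (default 5).
#' @param seed Base seed.
#' @param mcc_mode MCC mode for selection (default `"include_all"`).
#' @return Named list of `eval_report`s: `svm`, `mcc_svm`, `lstm`,
#'   `mcc_lstm`, plus `selection` (the `feature_selection` used).
#' @export
architecture_grid <- function(iaf, events, rule = ">0.6",
                              svm_config = list(), lstm_config = list(),
                              train_fraction = 0.75, n_repeats = 5L,
                              seed = 1L, mcc_mode = "include_all") {
  labels <- make_window_labels(events, iaf$window_start_times,
                               window_s = iaf$window_s)
  split <- split_train_test(iaf, labels, events, train_fraction)
  ep <- epoch_features(iaf, split$train_events)
  sel <- select_features(mcc(ep, mode = mcc_mode), rule)
  fid <- feature_ids(iaf)
  list(
    svm = evaluate_decoder(split, "svm", fid, NULL, svm_config,
                           n_repeats, seed),
    mcc_svm = evaluate_decoder(split, "svm", fid, sel, svm_config,
                               n_repeats, seed),
    lstm = evaluate_decoder(split, "lstm", fid, NULL, lstm_config,
                            n_repeats, seed),
    mcc_lstm = evaluate_decoder(split, "lstm", fid, sel, lstm_config,
                                n_repeats, seed),
    selection = sel)
}

#' Render evaluation reports as a summary table
#'
#' @param reports Named list of `eval_report`s (e.g. from
#'   [architecture_grid()]).
#' @return Data frame with one row per architecture.
#' @export
report_table <- function(reports) {
  reports <- reports[vapply(reports, inherits, TRUE, "eval_report")]
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(architecture = nm, decoder = r$decoder,
               selection = r$selection, n_features = r$n_features,
               accuracy_mean = r$mean, accuracy_sd = r$sd,
               chance = r$chance, n_repeats = r$n_repeats,
               stringsAsFactors = FALSE)
  }))
}

#' Export per-window prediction traces as TSV
#'
#' @param report An `eval_report`.
#' @param window_start_times The IAF window grid (full recording).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(report, window_start_times, path) {
  df <- data.frame(window_time = window_start_times[report$test_idx],
                   true_label = report$test_y,
                   predicted_label = report$predictions)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
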