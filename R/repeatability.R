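#' Epoch IAF windows around cues
#'
#' Cuts the feature matrix into cue-aligned epochs running from the cue
#' onset to `post_offset_s` (default 400 ms) after the cue offset. The
#' epoch start is snapped to the latest window-grid start time at or before
#' the cue onset so epochs share one uniform grid; a 4 s cue thus spans
#' 0-4.4 s relative to onset, i.e. 22 windows of 200 ms.
#'
#' @param iaf An `iaf_matrix`.
#' @param events An `event_table`. Cue durations must be equal within each
#'   class (or pass `crop_to_min = TRUE` to crop to the class minimum).
#' @param post_offset_s Extension past the cue offset in seconds.
#' @param crop_to_min Crop unequal cue durations within a class to the
#'   class minimum instead of rejecting.
#' @return Object of class `epoch_set`: per class a trials x windows x
#'   features array, plus `rel_times` (per class), `features`, and a
#'   trial-to-event map.
#' @export
epoch_features <- function(iaf, events, post_offset_s = 0.4,
                           crop_to_min = FALSE) {
  ws <- iaf$window_s
  n_win <- nrow(iaf$values)
  classes <- unique(events$label)
  epochs <- list(); rel_times <- list(); trial_map <- list()
  for (cl in classes) {
    ev <- events[events$label == cl, , drop = FALSE]
    dur <- ev$offset_s - ev$onset_s
    if (max(dur) - min(dur) > 1e-9) {
      if (!crop_to_min)
        stop("unequal cue durations within class '", cl,
             "'; use crop_to_min = TRUE to crop")
      dur <- rep(min(dur), nrow(ev))
    }
    n_ep <- as.integer(round((dur[1L] + post_offset_s) / ws))
    start_idx <- floor(ev$onset_s / ws + 1e-9) + 1L
    keep <- start_idx + n_ep - 1L <= n_win
    if (!all(keep)) {
      warning(sum(!keep), " trial(s) of class '", cl,
              "' extend past the recording end; dropped")
      ev <- ev[keep, , drop = FALSE]
      start_idx <- start_idx[keep]
    }
    if (!nrow(ev)) next
    arr <- array(0, dim = c(nrow(ev), n_ep, ncol(iaf$values)))
    for (tr in seq_len(nrow(ev)))
      arr[tr, , ] <- iaf$values[start_idx[tr]:(start_idx[tr] + n_ep - 1L), ,
                                drop = FALSE]
    epochs[[cl]] <- arr
    rel_times[[cl]] <- (seq_len(n_ep) - 1L) * ws
    trial_map[[cl]] <- which(events$label == cl)[keep]
  }
  structure(list(epochs = epochs, rel_times = rel_times,
                 features = iaf$features, window_s = ws,
                 trial_map = trial_map),
            class = "epoch_set")
}

#' Composite temporal response (trial average)
#'
#' Averages the cue-aligned trials of each class, per feature and window,
#' producing the template against which single-trial repeatability is
#' measured.
#'
#' @param epochs An `epoch_set`.
#' @return List of class `composite_response`: per class a windows x
#'   features matrix, plus trial counts.
#' @export
composite_response <- function(epochs) {
  comp <- lapply(epochs$epochs, function(arr) {
    if (dim(arr)[1L] < 1L) stop("composite requires >= 1 trial")
    apply(arr, c(2L, 3L), mean)
  })
  structure(list(composite = comp,
                 n_trials = vapply(epochs$epochs, function(a) dim(a)[1L], 0L),
                 features = epochs$features, rel_times = epochs$rel_times),
            class = "composite_response")
}

#' Mean correlation coefficient (MCC) repeatability metric
#'
#' For every feature and class, correlates each trial's temporal response
#' with the composite (trial-averaged) response and averages the Pearson
#' coefficients over trials. Trials with zero variance are excluded from
#' the average, as are features whose composite has zero variance; a
#' feature with no valid trial left is flagged invalid. In
#' `"leave_one_out"` mode the composite is recomputed without the trial
#' being correlated, removing the self-correlation optimism of the default
#' `"include_all"` mode at small trial counts.
#'
#' @param epochs An `epoch_set` (epoch length >= 3 windows).
#' @param mode `"include_all"` (each trial correlates against the composite
#'   of all trials, the literal definition) or `"leave_one_out"`.
#' @return Data frame of class `mcc_table` with columns `class`, `feature`
#'   (`"<pair>|<band>"`), `pair`, `band`, `mcc`, `n_valid_trials`, `valid`.
#' @export
mcc <- function(epochs, mode = c("include_all", "leave_one_out")) {
  mode <- match.arg(mode)
  out <- list()
  feat_id <- paste(epochs$features$pair, epochs$features$band, sep = "|")
  for (cl in names(epochs$epochs)) {
    arr <- epochs$epochs[[cl]]
    n_tr <- dim(arr)[1L]; n_w <- dim(arr)[2L]; n_f <- dim(arr)[3L]
    if (n_w < 3L) stop("epoch length must be >= 3 windows")
    mcc_v <- rep(NA_real_, n_f)
    n_valid <- integer(n_f)
    tot <- apply(arr, c(2L, 3L), sum)
    for (f in seq_len(n_f)) {
      trials <- arr[, , f, drop = TRUE]
      if (n_tr == 1L) trials <- matrix(trials, nrow = 1L)
      rs <- numeric(0)
      for (tr in seq_len(n_tr)) {
        x <- trials[tr, ]
        if (stats::sd(x) == 0) next
        comp <- if (mode == "include_all") tot[, f] / n_tr
        else {
          if (n_tr < 2L) next
          (tot[, f] - x) / (n_tr - 1L)
        }
        if (stats::sd(comp) == 0) next
        rs <- c(rs, stats::cor(x, comp))
      }
      n_valid[f] <- length(rs)
      if (length(rs)) mcc_v[f] <- mean(rs)
    }
    out[[cl]] <- data.frame(class = cl, feature = feat_id,
                            pair = epochs$features$pair,
                            band = epochs$features$band,
                            mcc = mcc_v, n_valid_trials = n_valid,
                            valid = n_valid > 0L,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("mcc_table", "data.frame")
  tab
}

#' Parse a feature-selection rule string
#'
#' `">0.6"` selects features with MCC strictly greater than 0.6;
#' `"0.4:0.6"` selects MCC within the closed range \[0.4, 0.6\].
#'
#' @param rule Rule string, or a list with `threshold` or `range`.
#' @return Normalized list with either `threshold` or `range`.
#' @export
parse_selection_rule <- function(rule) {
  if (is.list(rule)) {
    if (!is.null(rule$threshold) || !is.null(rule$range)) return(rule)
    stop("rule list must contain `threshold` or `range`")
  }
  rule <- trimws(as.character(rule))
  if (grepl("^>", rule))
    return(list(threshold = as.numeric(sub("^>", "", rule))))
  if (grepl(":", rule)) {
    parts <- as.numeric(strsplit(rule, ":", fixed = TRUE)[[1L]])
    if (length(parts) != 2L || any(is.na(parts)) || parts[1L] > parts[2L])
      stop("range rule must be \"lo:hi\" with lo <= hi")
    return(list(range = parts))
  }
  stop("unrecognized selection rule: ", rule)
}

#' Select features by MCC repeatability
#'
#' Applies the rule per class (threshold: `mcc > t`, strict; range:
#' `lo <= mcc <= hi`) and returns the union of the per-class sets. Invalid
#' features are never selected. An empty selection is returned with a
#' warning (decoders refuse to train on it).
#'
#' @param mcc_table An `mcc_table`.
#' @param rule Selection rule (see [parse_selection_rule()]); default
#'   `">0.6"`.
#' @return Object of class `feature_selection`: `selected` (feature ids,
#'   union over classes), `per_class` (named list of per-class sets),
#'   `rule`.
#' @export
select_features <- function(mcc_table, rule = ">0.6") {
  rule <- parse_selection_rule(rule)
  per_class <- list()
  for (cl in unique(mcc_table$class)) {
    sub <- mcc_table[mcc_table$class == cl & mcc_table$valid, , drop = FALSE]
    hit <- if (!is.null(rule$threshold)) sub$mcc > rule$threshold
    else sub$mcc >= rule$range[1L] & sub$mcc <= rule$range[2L]
    per_class[[cl]] <- sub$feature[hit]
  }
  selected <- sort(unique(unlist(per_class)))
  if (!length(selected))
    warning("selection rule matched no feature")
  structure(list(selected = selected, per_class = per_class, rule = rule),
            class = "feature_selection")
}

#' Export an MCC table as TSV
#' @param mcc_table An `mcc_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mcc <- function(mcc_table, path) {
  utils::write.table(as.data.frame(mcc_table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a feature selection as JSON
#' @param selection A `feature_selection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(selection, path) {
  jsonlite::write_json(unclass(selection), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
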