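#' Read and validate a run configuration
#'
#' A run configuration is a YAML (or already-parsed list) with optional
#' stanzas: `simulate` ([synth_config()] arguments), `paths` (`edf`,
#'  `events` for pre-existing recordings), `features` (`window_s`,
#' `boxcar_s`, `standardize`), `selection` (`rule`, `mode`), `decode`
#' (`train_fraction`, `n_repeats`, `svm`, `lstm`), and `seed`. Either
#' `simulate` or `paths` must be present.
#'
#' @param config Path to a YAML file, or a list.
#' @return Validated config list of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML file or a list")
  if (is.null(config$simulate) &&
      (is.null(config$paths$edf) || is.null(config$paths$events)))
    stop("config needs either a `simulate` stanza or `paths` with edf and events")
  config$seed <- as.integer(config$seed %||% 1L)
  config$selection$rule <- config$selection$rule %||% ">0.6"
  config$decode$train_fraction <- config$decode$train_fraction %||% 0.75
  config$decode$n_repeats <- config$decode$n_repeats %||% 5L
  class(config) <- c("run_config", "list")
  config
}

#' Run the full decoding pipeline
#'
#' Orchestrates simulate (or load) -> bipolar montage -> IAF extraction ->
#' MCC feature selection -> four-architecture decoding, writing every
#' artifact (EDF, events TSV, ground-truth JSON, IAF TSV, MCC TSV,
#' selection JSON, report TSV, prediction traces, config copy with content
#' hash, log) into the run directory. Deterministic given the config and
#' seed: a rerun writes byte-identical tables.
#'
#' @param config A `run_config`, YAML path, or list (see
#'   [read_run_config()]).
#' @param out_dir Output directory (created if needed); overrides
#'   `config$out_dir`.
#' @return Invisibly, a list with the run artifacts (`reports`, `selection`,
#'   `mcc`, `iaf`, paths).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- read_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  logf("stage config: hash %s", cfg_hash)

  stage <- function(name, expr) {
    logf("stage %s: start", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      sc <- do.call(synth_config,
                    c(config$simulate[setdiff(names(config$simulate), "seed")],
                      list(seed = config$simulate$seed %||% config$seed)))
      simulate_recording(sc)
    })
    stage("write-inputs", {
      write_edf(sim$recording, file.path(out_dir, "recording.edf"))
      write_events(sim$events, file.path(out_dir, "events.tsv"))
      write_ground_truth(sim$truth, file.path(out_dir, "ground_truth.json"))
    })
    truth <- sim$truth
    edf_path <- file.path(out_dir, "recording.edf")
    events_path <- file.path(out_dir, "events.tsv")
  } else {
    edf_path <- config$paths$edf
    events_path <- config$paths$events
  }

  recording <- stage("read", read_edf(edf_path))
  events <- stage("read", read_events(events_path))

  iaf <- stage("extract", {
    montage <- build_bipolar_montage(recording)
    write_montage(montage, file.path(out_dir, "montage.tsv"))
    extract_iaf(recording, montage,
                window_s = config$features$window_s %||% 0.2,
                boxcar_s = config$features$boxcar_s %||% 1.0,
                standardize = config$features$standardize %||% TRUE)
  })
  write_iaf(iaf, file.path(out_dir, "iaf.tsv"))

  reports <- stage("decode", {
    do.call(architecture_grid, list(
      iaf = iaf, events = events,
      rule = config$selection$rule,
      svm_config = config$decode$svm %||% list(),
      lstm_config = config$decode$lstm %||% list(),
      train_fraction = config$decode$train_fraction,
      n_repeats = config$decode$n_repeats,
      seed = config$seed,
      mcc_mode = config$selection$mode %||% "include_all"))
  })

  stage("report", {
    mcc_tab <- mcc(epoch_features(iaf, events))
    write_mcc(mcc_tab, file.path(out_dir, "mcc.tsv"))
    write_selection(reports$selection, file.path(out_dir, "selection.json"))
    tab <- report_table(reports)
    tab$config_hash <- cfg_hash
    utils::write.table(tab, file.path(out_dir, "report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (nm in setdiff(names(reports), "selection"))
      write_predictions(reports[[nm]], iaf$window_start_times,
                        file.path(out_dir, paste0("predictions_", nm, ".tsv")))
  })
  logf("run complete: %s", out_dir)
  invisible(list(reports = reports, selection = reports$selection,
                 iaf = iaf, truth = truth, out_dir = out_dir,
                 config_hash = cfg_hash))
}

#' Quick synthetic end-to-end demo configuration
#'
#' A small configuration (reduced sampling rate, few trials) that runs the
#' full pipeline in minutes on a single CPU.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return A `run_config`.
#' @export
demo_config <- function(seed = 1L, out_dir = tempfile("seegdecode_demo")) {
  read_run_config(list(
    out_dir = out_dir, seed = seed,
    simulate = list(sampling_rate = 500, n_leads = 2L,
                    contacts_per_lead = 8L,
                    classes = c("thumb", "middle"),
                    trials_per_class = 10L,
                    effect_size = 4, amplitude_jitter_cv = 0.2),
    selection = list(rule = ">0.6"),
    decode = list(n_repeats = 2L,
                  svm = list(gamma = NULL, cost = 1),
                  lstm = list(hidden = 24L, epochs = 60L))))
}
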