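# End-to-end experiment orchestration: simulate -> preprocess -> featurize ->
# train -> evaluate -> report, driven by a single validated configuration, plus
# named presets mirroring the study's experimental grids at desk scale.

#' Build and validate an experiment configuration
#'
#' Precedence for the command-line tool is CLI flag > config file > these
#' defaults.  Validation rejects inconsistent pairings (contextual stacking
#' or the deep spectral models with a non-spectral representation).
#'
#' @param representation `"fft"`, `"mazilu"` or `"mfcc"`.
#' @param context previous windows stacked with each window (0-3, fft only).
#' @param overlap window overlap fraction (0, 0.5 or 0.75).
#' @param model detector kind (see [loso_evaluate()]).
#' @param scheme `"loso"` or `"r10fold"`.
#' @param repeats LOSO repeats.
#' @param folds R10fold fold count.
#' @param n_subjects,recording_minutes,recordings_per_subject,fog_fraction,fog_contrast
#'   simulator settings (see [cohort_spec()]).
#' @param epochs,batch_size optional overrides for the deep detectors.
#' @param n_estimators ensemble size for shallow ensembles.
#' @param seed master seed; simulation, fold and training seeds derive from it.
#' @param out_dir artifact directory, or `NULL` for none.
#' @param dry_run validate and return without computing.
#' @return a validated `fog_experiment_config` list.
#' @export
experiment_config <- function(representation = "fft", context = 0L,
                              overlap = 0.75, model = "random_forest",
                              scheme = "loso", repeats = 1L, folds = 10L,
                              n_subjects = 6L, recording_minutes = 8,
                              recordings_per_subject = 1L,
                              fog_fraction = 0.105, fog_contrast = 1,
                              epochs = NULL, batch_size = NULL,
                              n_estimators = 100L, seed = 1L, out_dir = NULL,
                              dry_run = FALSE) {
  cfg <- list(representation = representation, context = as.integer(context),
              overlap = overlap, model = model, scheme = scheme,
              repeats = as.integer(repeats), folds = as.integer(folds),
              n_subjects = as.integer(n_subjects),
              recording_minutes = recording_minutes,
              recordings_per_subject = as.integer(recordings_per_subject),
              fog_fraction = fog_fraction, fog_contrast = fog_contrast,
              epochs = epochs, batch_size = batch_size,
              n_estimators = as.integer(n_estimators), seed = as.integer(seed),
              out_dir = out_dir, dry_run = isTRUE(dry_run))
  err <- function(...) stop(structure(class = c("fog_config_error", "error",
                                                "condition"),
                                      list(message = paste0(...),
                                           call = sys.call(-1))))
  if (!cfg$representation %in% c("fft", "mazilu", "mfcc"))
    err("unknown representation: ", cfg$representation)
  if (!cfg$model %in% c("cnn_lstm", "cnn", "mlp_autoencoder", "ocsvm", "svm",
                        "adaboost", "random_forest"))
    err("unknown model: ", cfg$model)
  if (!cfg$scheme %in% c("loso", "r10fold")) err("unknown scheme: ", cfg$scheme)
  if (!cfg$overlap %in% c(0, 0.5, 0.75)) err("overlap must be 0, 0.5 or 0.75")
  if (cfg$context < 0L || cfg$context > 3L) err("context must be in 0..3")
  if (cfg$context > 0L && cfg$representation != "fft")
    err("contextual windows require the fft representation")
  if (cfg$model %in% c("cnn", "cnn_lstm", "mlp_autoencoder") &&
      cfg$representation != "fft")
    err("model ", cfg$model, " requires the fft (spectral) representation")
  if (cfg$model != "cnn_lstm" && cfg$context > 0L)
    err("only cnn_lstm consumes stacked contextual windows")
  structure(cfg, class = "fog_experiment_config")
}

#' Run one experiment end to end
#'
#' Simulates the configured synthetic cohort, preprocesses every recording
#' (40 Hz, band limiting, windowing with the discard tally logged), computes
#' the feature representation, evaluates the model under the configured
#' scheme and, when `out_dir` is set, writes report artifacts plus a
#' resolved-config snapshot.
#'
#' @param cfg a `fog_experiment_config`.
#' @param quiet suppress per-stage log messages.
#' @return list: `config`, `windows` summary, `eval` (a `fog_eval` or list of
#'   per-subject reports), `artifacts` (paths, possibly empty).
#' @export
run_experiment <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "fog_experiment_config"))
  log <- function(...) if (!quiet) message(sprintf(...))
  if (cfg$dry_run) {
    log("dry run: configuration valid")
    return(list(config = cfg, eval = NULL, artifacts = character(0)))
  }
  spec <- cohort_spec(n_subjects = cfg$n_subjects,
                      recording_minutes = cfg$recording_minutes,
                      recordings_per_subject = cfg$recordings_per_subject,
                      target_fog_fraction = cfg$fog_fraction,
                      fog_contrast = cfg$fog_contrast, seed = cfg$seed)
  recs <- simulate_cohort(spec)
  log("simulated %d recording(s), %d subject(s), FOG fraction %.3f",
      length(recs), cfg$n_subjects,
      attr(recs, "manifest")$realized_fog_fraction)
  ws <- bind_windows(lapply(recs, preprocess_recording, overlap = cfg$overlap))
  log("windows: %d kept (%d FOG / %d non-FOG), %d mixed discarded of %d enumerated",
      length(ws$labels), sum(ws$labels), sum(ws$labels == 0), ws$n_discarded,
      ws$n_enumerated)
  feats <- featurize(ws, cfg$representation, cfg$context)
  log("features: %s k=%d -> %d x %d", cfg$representation, cfg$context,
      nrow(feats$values), ncol(feats$values))
  tcfg <- train_config(epochs = cfg$epochs, batch_size = cfg$batch_size,
                       seed = cfg$seed)
  ev <- if (cfg$scheme == "loso") {
    loso_evaluate(feats, cfg$model, repeats = cfg$repeats, seed = cfg$seed,
                  cfg = tcfg, n_estimators = cfg$n_estimators)
  } else {
    r10fold_cohort(feats, cfg$model, folds = cfg$folds, seed = cfg$seed,
                   cfg = tcfg, n_estimators = cfg$n_estimators)
  }
  arts <- character(0)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    snap <- file.path(cfg$out_dir, "config.json")
    jsonlite::write_json(unclass(cfg), snap, auto_unbox = TRUE, null = "null")
    evs <- if (inherits(ev, "fog_eval")) list(ev) else ev
    arts <- c(snap, report(evs, cfg$out_dir))
  }
  agg <- if (inherits(ev, "fog_eval")) ev$aggregate else attr(ev, "aggregate")
  log("aggregate: %s", paste(sprintf("%s=%.3f", names(agg), agg),
                             collapse = " "))
  list(config = cfg, eval = ev, artifacts = arts)
}

#' Named experiment presets (desk-scale grids)
#'
#' Each preset returns the list of configurations spanning one of the
#' standard experimental grids, scaled to a 6-subject, 8-minute synthetic
#' cohort with shortened deep-model training so a grid finishes on one CPU:
#' \describe{
#'   \item{table3}{R10fold, random forest, 3 representations x 3 overlaps.}
#'   \item{table4}{LOSO, random forest, 3 representations x 3 overlaps.}
#'   \item{table5}{LOSO novelty detectors (ocsvm, autoencoder), fft, 75 percent overlap.}
#'   \item{table6}{LOSO supervised models (svm, adaboost, random forest,
#'     cnn, cnn_lstm), fft, 75 percent overlap.}
#'   \item{table7}{LOSO cnn_lstm at context depths 0-3, fft, 75 percent overlap.}
#' }
#'
#' @param name preset name.
#' @param seed master seed applied to every config in the grid.
#' @return list of `fog_experiment_config`s.
#' @export
experiment_preset <- function(name, seed = 1L) {
  base <- function(...) experiment_config(..., n_subjects = 6L,
                                          recording_minutes = 8,
                                          repeats = 1L, epochs = 12L,
                                          batch_size = 256L, seed = seed)
  switch(name,
    table3 = {
      g <- expand.grid(rep = c("mazilu", "mfcc", "fft"),
                       ov = c(0, 0.5, 0.75), stringsAsFactors = FALSE)
      lapply(seq_len(nrow(g)), function(i)
        base(representation = g$rep[i], overlap = g$ov[i], scheme = "r10fold",
             model = "random_forest"))
    },
    table4 = {
      g <- expand.grid(rep = c("mazilu", "mfcc", "fft"),
                       ov = c(0, 0.5, 0.75), stringsAsFactors = FALSE)
      lapply(seq_len(nrow(g)), function(i)
        base(representation = g$rep[i], overlap = g$ov[i], scheme = "loso",
             model = "random_forest"))
    },
    table5 = lapply(c("ocsvm", "mlp_autoencoder"), function(m)
      base(model = m, scheme = "loso")),
    table6 = lapply(c("svm", "adaboost", "random_forest", "cnn", "cnn_lstm"),
                    function(m) base(model = m, scheme = "loso")),
    table7 = lapply(0:3, function(k)
      base(model = "cnn_lstm", context = k, scheme = "loso")),
    stop(structure(class = c("fog_config_error", "error", "condition"),
                   list(message = paste0("unknown preset: ", name),
                        call = sys.call())))
  )
}

#' Run a preset grid and collect one summary row per configuration
#'
#' @param name preset name (see [experiment_preset()]).
#' @param seed master seed.
#' @param out_dir artifact directory or `NULL`.
#' @param quiet suppress logs.
#' @return data.frame with one row per grid entry and the aggregate metrics.
#' @export
run_preset <- function(name, seed = 1L, out_dir = NULL, quiet = FALSE) {
  cfgs <- experiment_preset(name, seed)
  rows <- lapply(cfgs, function(cf) {
    if (!is.null(out_dir))
      cf$out_dir <- file.path(out_dir, sprintf("%s_%s_k%d_ov%g", name,
                                               cf$model, cf$context,
                                               cf$overlap))
    res <- run_experiment(cf, quiet = quiet)
    agg <- if (inherits(res$eval, "fog_eval")) res$eval$aggregate
           else attr(res$eval, "aggregate")
    cbind(data.frame(preset = name, model = cf$model,
                     representation = cf$representation, context = cf$context,
                     overlap = cf$overlap, scheme = cf$scheme),
          as.data.frame(as.list(agg)))
  })
  do.call(rbind, rows)
}
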