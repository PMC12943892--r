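#' Validate a pipeline configuration
#'
#' Checks a nested configuration (a YAML file path or an already-parsed
#' list) against the published schema: unknown keys are rejected with a
#' nearest-valid-key suggestion, values are type- and range-checked, and
#' missing entries are filled with the documented defaults.
#'
#' @param config Path to a YAML file, or a nested list.
#' @return A validated `run_config` list with all defaults filled.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a YAML mapping (a named list)")
  schema <- config_schema()
  errors <- character(0)
  out <- check_block(config, schema, path = "", errors)
  if (length(out$errors))
    stop("invalid configuration:\n  - ",
         paste(out$errors, collapse = "\n  - "))
  structure(out$value, class = "run_config")
}

config_schema <- function() {
  num <- function(default, lo = -Inf, hi = Inf)
    list(kind = "number", default = default, lo = lo, hi = hi)
  int <- function(default, lo = -Inf, hi = Inf)
    list(kind = "integer", default = default, lo = lo, hi = hi)
  flag <- function(default) list(kind = "flag", default = default)
  list(
    seed = int(1L),
    stages = list(kind = "stages",
                  default = c("simulate", "denoise", "features",
                              "train", "evaluate")),
    stft = list(window_ms = num(64, 1), overlap_fraction = num(0.5, 0, 0.999)),
    mcra = list(alpha_s = num(0.8, 1e-6, 1 - 1e-6),
                delta_ratio = num(2, 1 + 1e-9),
                alpha_p = num(0.2, 1e-6, 1 - 1e-6),
                alpha_floor = num(0.95, 1e-6, 1 - 1e-6),
                vmin_frames = int(600L, 1)),
    gevd = list(alpha_y = num(0.9, 0, 0.999),
                threshold_eps = num(5, 1e-9)),
    gain = list(mu_min = num(1, 0), mu_max = num(1201, 0),
                snr_high_db = num(20), snr_low_db = num(-5)),
    features = list(window_s = num(1, 1e-3), pad_to_T = int(64L, 1),
                    q_over_r = num(0.1, 1e-9)),
    backbone = list(top_k = int(10L, 1, 62L), gcn_dim = int(16L, 1),
                    head_dim = int(16L, 1), heads = int(4L, 1)),
    train = list(lr = num(0.001, 1e-9), batch_size = int(64L, 1),
                 epochs = int(200L, 1), dropout = num(0.1, 0, 0.999),
                 label_smoothing = num(0.1, 0, 0.999)),
    simulate = list(n_channels = int(62L, 1), fs = num(200, 1),
                    duration_s = num(60, 0.1),
                    target_snr_db = num(0),
                    spike_rate = num(0.5, 0),
                    n_subjects = int(9L, 2), trials_per_subject = int(10L, 1),
                    n_classes = int(3L, 2), n_frames = int(8L, 1))
  )
}

check_block <- function(value, schema, path, errors) {
  known <- names(schema)
  for (key in names(value)) {
    if (!key %in% known) {
      sugg <- known[which.min(utils::adist(key, known))]
      errors <- c(errors, paste0("unknown key '", paste0(path, key),
                                 "'; did you mean '", paste0(path, sugg),
                                 "'?"))
    }
  }
  out <- list()
  for (key in known) {
    spec <- schema[[key]]
    given <- value[[key]]
    if (!is.null(spec$kind)) {
      r <- check_leaf(given, spec, paste0(path, key))
      out[[key]] <- r$value
      errors <- c(errors, r$errors)
    } else {
      sub <- check_block(if (is.null(given)) list() else given, spec,
                         paste0(path, key, "."), character(0))
      out[[key]] <- sub$value
      errors <- c(errors, sub$errors)
    }
  }
  list(value = out, errors = errors)
}

check_leaf <- function(given, spec, path) {
  if (is.null(given)) return(list(value = spec$default, errors = character(0)))
  if (spec$kind == "stages") {
    allowed <- c("simulate", "denoise", "features", "train", "evaluate")
    bad <- setdiff(given, allowed)
    if (length(bad))
      return(list(value = spec$default,
                  errors = paste0(path, ": unknown stage(s) ",
                                  paste(bad, collapse = ", "))))
    return(list(value = given, errors = character(0)))
  }
  if (spec$kind == "flag") {
    if (!is.logical(given) || length(given) != 1L)
      return(list(value = spec$default,
                  errors = paste0(path, " must be true/false")))
    return(list(value = given, errors = character(0)))
  }
  if (!is.numeric(given) || length(given) != 1L || !is.finite(given))
    return(list(value = spec$default,
                errors = paste0(path, " must be a single finite number")))
  if (given < spec$lo || given > spec$hi)
    return(list(value = spec$default,
                errors = paste0(path, " = ", given, " outside [",
                                spec$lo, ", ", spec$hi, "]")))
  v <- if (spec$kind == "integer") as.integer(round(given)) else given
  list(value = v, errors = character(0))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages in order — simulate (paired synthetic
#' scene + labeled feature set), denoise (MIMO subspace filtering of the
#' noisy scene), features (band differential-entropy tensor from the
#' denoised recording), train (model fit on the labeled feature set) and
#' evaluate (LOSO metric suite) — writing each stage's outputs plus a JSON
#' run manifest (config hash, package version, seed, per-stage summaries)
#' into `out_dir`. Disabling the denoise stage runs the no-noise-reduction
#' ablation arm and tags the manifest accordingly.
#'
#' @param config A `run_config` from [validate_config()] (or anything it
#'   accepts).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly also written to
#'   `file.path(out_dir, "manifest.json")`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("eegfuse_run_")) {
  cfg <- validate_config(unclass_config(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "eegfuse",
    version = as.character(utils::packageVersion("eegfuse")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    stages = list(),
    ablation = if (!"denoise" %in% cfg$stages) "w/o NR" else "full"
  )
  stages <- cfg$stages
  art <- list()

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- res$summary
    art <<- utils::modifyList(art, res$artifacts)
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    sc <- scene_config(n_channels = cfg$simulate$n_channels,
                       fs = cfg$simulate$fs,
                       duration_s = cfg$simulate$duration_s,
                       target_snr_db = cfg$simulate$target_snr_db,
                       spike_rate = cfg$simulate$spike_rate,
                       seed = cfg$seed)
    rec <- generate_recording(sc)
    lf <- generate_labeled_features(labeled_feature_spec(
      n_subjects = cfg$simulate$n_subjects,
      trials_per_subject = cfg$simulate$trials_per_subject,
      n_classes = cfg$simulate$n_classes,
      n_channels = cfg$simulate$n_channels,
      n_frames = cfg$simulate$n_frames,
      seed = cfg$seed + 1L))
    saveRDS(rec, file.path(out_dir, "scene.rds"))
    saveRDS(lf, file.path(out_dir, "labeled_features.rds"))
    utils::write.csv(data.frame(trial_id = seq_along(lf$labels),
                                subject_id = lf$subjects,
                                label = lf$labels),
                     file.path(out_dir, "labels.csv"), row.names = FALSE)
    list(summary = list(realized_snr_db = rec$metadata$realized_snr_db,
                        n_trials = length(lf$labels)),
         artifacts = list(rec = rec, lf = lf))
  })

  if ("denoise" %in% stages) run_stage("denoise", function() {
    if (is.null(art$rec)) art$rec <- readRDS(file.path(out_dir, "scene.rds"))
    sc_cfg <- stft_config(art$rec$metadata$config$fs,
                          window_ms = cfg$stft$window_ms,
                          overlap_fraction = cfg$stft$overlap_fraction)
    dn <- denoise_recording(
      art$rec$noisy, art$rec$metadata$config$fs, config = sc_cfg,
      reference = art$rec$clean,
      mcra = mcra_params(alpha_s = cfg$mcra$alpha_s,
                         delta_ratio = cfg$mcra$delta_ratio,
                         alpha_p = cfg$mcra$alpha_p,
                         alpha_floor = cfg$mcra$alpha_floor,
                         vmin_frames = cfg$mcra$vmin_frames),
      schedule = gain_schedule(mu_min = cfg$gain$mu_min,
                               mu_max = cfg$gain$mu_max,
                               snr_high_db = cfg$gain$snr_high_db,
                               snr_low_db = cfg$gain$snr_low_db),
      rule = subspace_rule(threshold_eps = cfg$gevd$threshold_eps),
      alpha_y = cfg$gevd$alpha_y)
    saveRDS(dn$denoised, file.path(out_dir, "denoised.rds"))
    list(summary = list(snr_in_db = dn$snr_in_db,
                        snr_out_db = dn$snr_out_db,
                        snr_gain_db = dn$snr_out_db - dn$snr_in_db,
                        n_skipped = dn$diagnostics$n_skipped),
         artifacts = list(denoised = dn$denoised))
  })

  if ("features" %in% stages) run_stage("features", function() {
    if (is.null(art$rec)) art$rec <- readRDS(file.path(out_dir, "scene.rds"))
    x <- if (!is.null(art$denoised)) art$denoised else art$rec$noisy
    fs <- art$rec$metadata$config$fs
    n_frames <- floor(ncol(x) / (cfg$features$window_s * fs))
    ft <- build_feature_tensor(list(x), labels = 1L, fs = fs,
                               window_s = cfg$features$window_s,
                               pad_to_T = max(cfg$features$pad_to_T,
                                              n_frames),
                               q_over_r = cfg$features$q_over_r)
    saveRDS(ft, file.path(out_dir, "features.rds"))
    list(summary = list(frames = ft$trial_lengths[1L]),
         artifacts = list(ft = ft))
  })

  if ("train" %in% stages) run_stage("train", function() {
    if (is.null(art$lf))
      art$lf <- readRDS(file.path(out_dir, "labeled_features.rds"))
    tc <- train_config(lr = cfg$train$lr, batch_size = cfg$train$batch_size,
                       epochs = cfg$train$epochs,
                       dropout = cfg$train$dropout,
                       label_smoothing = cfg$train$label_smoothing,
                       seed = cfg$seed)
    fit <- train_model(art$lf$features, art$lf$labels, config = tc)
    saveRDS(fit$model, file.path(out_dir, "model.rds"))
    list(summary = list(final_loss = utils::tail(fit$history$loss, 1L),
                        final_train_acc = utils::tail(fit$history$accuracy,
                                                      1L),
                        lr = tc$lr, batch = tc$batch_size,
                        epochs = tc$epochs),
         artifacts = list(fit = fit))
  })

  if ("evaluate" %in% stages) run_stage("evaluate", function() {
    if (is.null(art$lf))
      art$lf <- readRDS(file.path(out_dir, "labeled_features.rds"))
    tc <- train_config(lr = cfg$train$lr, batch_size = cfg$train$batch_size,
                       epochs = cfg$train$epochs,
                       dropout = cfg$train$dropout,
                       label_smoothing = cfg$train$label_smoothing,
                       seed = cfg$seed)
    ev <- loso_evaluate(art$lf$features, art$lf$labels, art$lf$subjects,
                        config = tc)
    utils::write.csv(ev$folds, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    list(summary = list(mean_accuracy = unname(ev$mean["accuracy"]),
                        mean_mcc = unname(ev$mean["mcc"]),
                        mean_f1 = unname(ev$mean["f1"]),
                        sd_accuracy = unname(ev$sd["accuracy"])),
         artifacts = list(ev = ev))
  })

  for (s in c("simulate", "denoise", "features", "train", "evaluate"))
    if (!s %in% stages && is.null(manifest$stages[[s]]))
      manifest$stages[[s]] <- "skipped"

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

unclass_config <- function(config) {
  if (inherits(config, "run_config")) unclass(config) else config
}

#' Write / read a multichannel recording as plain text
#'
#' Recordings travel as a channels x samples CSV plus a JSON sidecar
#' carrying the sampling rate and provenance (package version, config hash
#' if given).
#'
#' @param x `M x N` matrix.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @param sample_rate Sampling rate in Hz.
#' @param extra Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_recording <- function(x, path, sample_rate, extra = list()) {
  utils::write.table(x, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- c(list(sample_rate = sample_rate,
                 n_channels = nrow(x), n_samples = ncol(x),
                 package = "eegfuse",
                 version = as.character(utils::packageVersion("eegfuse"))),
            extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @return For `read_recording`, a list with `data` (`M x N` matrix) and
#'   `meta` (the sidecar list).
#' @export
read_recording <- function(path) {
  x <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(x) <- NULL
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else
    list()
  list(data = x, meta = meta)
}
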