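# End-to-end reproducible pipeline: simulate -> split -> train -> evaluate.
# Every stage writes its artifact plus the resolved configuration; re-runs
# with an identical configuration reuse cached artifacts. All randomness
# flows from the single `seed` through named sub-streams.

#' Default pipeline configuration
#'
#' A compact configuration tree covering every stage. The defaults describe
#' a small smoke-scale run; the full-scale values (192 px crops, full
#' geometry, 200-epoch cap) are reachable by overriding fields.
#'
#' @param seed global seed.
#' @param out_dir output directory.
#' @return nested configuration list (`run_config`).
#' @export
default_run_config <- function(seed = 1L, out_dir = "biraster_run") {
  list(seed = as.integer(seed), out_dir = out_dir,
       simulate = list(n_pairs = 20L, crop_size = 64L, n_vessels = 6L,
                       noise_sd = 0.0045),
       geometry = list(fov_x_mm = 1.1, fov_y_mm = 1.0, n_fast = 250L,
                       y_step_um = 4),
       jitter = list(phase_lag_mean = 0.004, phase_lag_sd = 0.002,
                     distortion_coeffs = 0.003, drift_amplitude = 0.002),
       model = list(n_scales = 3L, base_channels = 8L, growth_rate = 8L,
                    dense_layers_per_block = 2L, disc_base_width = 12L),
       train = list(epochs_max = 5L, batch_size = 4L, lambda = 0.05,
                    nu = 0.60, lr_g = 2e-4, lr_d = 2e-4),
       evaluate = list(baselines = c("bicubic", "bilateral", "median")))
}

#' Load a pipeline configuration from YAML
#'
#' Fields present in the file override [default_run_config()]; everything
#' else keeps its default.
#'
#' @param path YAML file.
#' @param seed,out_dir optional overrides applied after the file.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path, seed = NULL, out_dir = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- modifyList(cfg, user)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  cfg
}

stage_cached <- function(stamp_path, cfg_json, artifacts) {
  file.exists(stamp_path) &&
    identical(readLines(stamp_path, warn = FALSE), cfg_json) &&
    all(file.exists(artifacts))
}

write_stamp <- function(stamp_path, cfg_json) writeLines(cfg_json, stamp_path)

#' Run the full simulate/train/evaluate pipeline
#'
#' Stages: (1) simulate a paired dataset, (2) split it, (3) train the GAN
#' with SSIM checkpointing, (4) evaluate the trained model and the classical
#' baselines on the test split, writing the benchmark-table CSV. Each stage
#' is resumable: if its artifact exists and was produced under the same
#' resolved configuration, it is reused.
#'
#' @param config a [default_run_config()]-shaped list.
#' @param verbose print stage progress.
#' @return named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), verbose = TRUE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  cfg_json <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
  yaml::write_yaml(config, file.path(config$out_dir, "resolved_config.yaml"))

  geometry <- do.call(scan_geometry, config$geometry)
  jit <- do.call(jitter_model, c(config$jitter, list(seed = sub_seed(config$seed, 1L))))

  # --- simulate ---
  data_dir <- file.path(config$out_dir, "dataset")
  st <- file.path(config$out_dir, "stamp_simulate.json")
  if (stage_cached(st, cfg_json, file.path(data_dir, "manifest.json"))) {
    say("[simulate] cached")
    dataset <- read_paired_dataset(data_dir)
  } else {
    say("[simulate] generating ", config$simulate$n_pairs, " pairs")
    dataset <- generate_paired_dataset(
      config$simulate$n_pairs, geometry, jit, seed = sub_seed(config$seed, 2L),
      crop_size = config$simulate$crop_size,
      n_vessels = config$simulate$n_vessels,
      noise_sd = config$simulate$noise_sd)
    write_paired_dataset(dataset, data_dir)
    write_stamp(st, cfg_json)
  }

  # --- split ---
  split_path <- file.path(config$out_dir, "split.json")
  split <- split_dataset(length(dataset$pairs), seed = sub_seed(config$seed, 3L))
  jsonlite::write_json(unclass(split), split_path, auto_unbox = FALSE, digits = NA)

  # --- train ---
  ckpt_path <- file.path(config$out_dir, "checkpoint.rds")
  st <- file.path(config$out_dir, "stamp_train.json")
  if (stage_cached(st, cfg_json, ckpt_path)) {
    say("[train] cached")
    ckpt <- load_checkpoint(ckpt_path)
  } else {
    say("[train] ", config$train$epochs_max, " epochs")
    gen <- build_generator(generator_config(
      n_scales = config$model$n_scales,
      dense_layers_per_block = config$model$dense_layers_per_block,
      growth_rate = config$model$growth_rate,
      base_channels = config$model$base_channels,
      init_seed = sub_seed(config$seed, 4L)))
    disc <- build_discriminator(discriminator_config(
      base_width = config$model$disc_base_width,
      init_seed = sub_seed(config$seed, 5L)))
    tc <- train_config(epochs_max = config$train$epochs_max,
                       batch_size = config$train$batch_size,
                       lr_g = config$train$lr_g, lr_d = config$train$lr_d,
                       lambda = config$train$lambda, nu = config$train$nu,
                       seed = sub_seed(config$seed, 6L))
    ckpt <- train_gan(gen, disc, dataset, split, tc, verbose = verbose)
    save_checkpoint(ckpt, ckpt_path)
    utils::write.csv(ckpt$log, file.path(config$out_dir, "training_log.csv"),
                     row.names = FALSE)
    write_stamp(st, cfg_json)
  }

  # --- evaluate ---
  report_csv <- file.path(config$out_dir, "report.csv")
  report_json <- file.path(config$out_dir, "report_per_image.json")
  methods <- list(model = function(x) infer(ckpt, x))
  for (b in config$evaluate$baselines)
    methods[[b]] <- local({
      bb <- b
      function(x) baseline_filter(x, bb)
    })
  say("[evaluate] ", length(split$test), " test pairs, ",
      length(methods) + 1L, " method columns")
  report <- evaluate_set(dataset$pairs[split$test], methods)
  write_metric_report(report, report_csv, report_json)

  invisible(list(dataset = data_dir, split = split_path,
                 checkpoint = ckpt_path, report = report_csv,
                 config = file.path(config$out_dir, "resolved_config.yaml"),
                 metric_report = report))
}
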