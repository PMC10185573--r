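#' Default pipeline configuration
#'
#' A complete, schema-valid [run_pipeline()] configuration for a fully
#' synthetic run: an imbalanced calibration campaign is simulated from the
#' forward model, prepared (balanced, split 80:20), used to train the
#' three-layer cascade, evaluated (hold-out and optional k-fold CV), and
#' applied to a simulated pH-gradient scene.
#'
#' @param outdir Artifact directory.
#' @param seed Master seed; per-stage seeds are derived deterministically.
#' @return Named list understood by [run_pipeline()].
#' @export
default_config <- function(outdir = tempfile("optodecast_run"), seed = 1) {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    grid = list(start = 470, stop = 900, step = 3),
    params = list(),                    # spectral_model_params() overrides
    simulate = list(preset = "imbalanced", base = 25,
                    ph_points = seq(4, 11, by = 1),
                    po2_points = c(0, 5, 10, 20, 50, 100, 150, 195)),
    prepare = list(balance = TRUE, split = 0.8),
    train = list(conditioning = "oof",
                 cfg_ph = list(), cfg_o2 = list()),   # gbt_config overrides
    evaluate = list(cv = 0),            # k>1 enables k-fold CV
    scene = list(height = 40, width = 60, ph = c(5, 9), po2 = 100)
  )
}

validate_config <- function(config) {
  required <- c("outdir", "seed", "grid", "simulate", "prepare", "train",
                "evaluate", "scene")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0)
    stop("run_pipeline: config is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!is.numeric(config$seed) || length(config$seed) != 1 ||
      !is.finite(config$seed))
    stop("run_pipeline: config$seed must be a single integer", call. = FALSE)
  invisible(config)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the full synthetic calibration workflow
#'
#' Wires the package stages end-to-end: simulate -> prepare -> train ->
#' evaluate -> predict-image. Every stage logs its input/output row
#' counts; all randomness derives from `config$seed`, so a rerun with the
#' same config reproduces every artifact. Stages whose artifacts already
#' exist in `config$outdir` are skipped unless `force = TRUE`, so a
#' partial run resumes at the first missing stage boundary.
#'
#' Artifacts written: `calibration.csv` (raw simulated table),
#' `train.csv` / `validation.csv`, `balance_report.json`, `model/`
#' (cascade artifact directory), `evaluation.json`, and `maps/` (chemical
#' image of the gradient scene).
#'
#' @param config Named list as produced by [default_config()], or a path
#'   to a YAML file with the same structure.
#' @param force Recompute stages whose artifacts already exist.
#' @return Invisibly, a list with the key in-memory artifacts
#'   (`table`, `train`, `validation`, `model`, `evaluation`, `image`).
#' @export
run_pipeline <- function(config = default_config(), force = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  grid <- do.call(wavelength_grid, config$grid)
  params <- do.call(spectral_model_params, config$params)

  # -- simulate ---------------------------------------------------------
  cal_path <- file.path(out, "calibration.csv")
  if (force || !file.exists(cal_path)) {
    design <- calibration_design(ph_points = config$simulate$ph_points,
                                 po2_points = config$simulate$po2_points,
                                 base = config$simulate$base,
                                 preset = config$simulate$preset)
    table <- generate_calibration_set(design, params = params, grid = grid,
                                      seed = config$seed)
    write_table(table, cal_path)
    stage_log("simulate", "%d calibration points -> %d samples",
              nrow(design), nrow(table))
  } else {
    table <- read_table(cal_path)
    stage_log("simulate", "resumed: %d samples from %s", nrow(table), cal_path)
  }

  # -- prepare ----------------------------------------------------------
  train_path <- file.path(out, "train.csv")
  val_path <- file.path(out, "validation.csv")
  if (force || !file.exists(train_path) || !file.exists(val_path)) {
    prepared <- table
    if (isTRUE(config$prepare$balance)) {
      bal <- balance_table(table)
      prepared <- bal$table
      jsonlite::write_json(
        list(target = attr(bal$report, "target"), points = bal$report),
        file.path(out, "balance_report.json"), digits = NA)
      stage_log("prepare", "balanced %d -> %d samples (target %d/point)",
                nrow(table), nrow(prepared), attr(bal$report, "target"))
    }
    split <- split_table(prepared, ratio = config$prepare$split,
                         seed = config$seed + 1L)
    write_table(split$train, train_path)
    write_table(split$validation, val_path)
    stage_log("prepare", "split %d -> %d train / %d validation",
              nrow(prepared), nrow(split$train), nrow(split$validation))
  } else {
    split <- list(train = read_table(train_path),
                  validation = read_table(val_path))
    stage_log("prepare", "resumed: %d train / %d validation",
              nrow(split$train), nrow(split$validation))
  }

  # -- train ------------------------------------------------------------
  model_dir <- file.path(out, "model")
  if (force || !file.exists(file.path(model_dir, "cascade.json"))) {
    cfg_ph <- do.call(gbt_config, utils::modifyList(
      unclass(gbt_config_ph()), config$train$cfg_ph))
    cfg_o2 <- do.call(gbt_config, utils::modifyList(
      unclass(gbt_config_o2()), config$train$cfg_o2))
    cfg_ph$seed <- config$seed + 2L; cfg_o2$seed <- config$seed + 3L
    model <- train_cascade(split$train, cfg_ph = cfg_ph, cfg_o2 = cfg_o2,
                           conditioning = config$train$conditioning)
    save_cascade(model, model_dir)
    stage_log("train", "cascade trained on %d rows, saved to %s",
              nrow(split$train), model_dir)
  } else {
    model <- load_cascade(model_dir)
    stage_log("train", "resumed: cascade loaded from %s", model_dir)
  }

  # -- evaluate ---------------------------------------------------------
  eval_path <- file.path(out, "evaluation.json")
  if (force || !file.exists(eval_path)) {
    pred <- predict_samples(model, table_spectra(split$validation))
    evaluation <- list(
      holdout = list(
        n = nrow(split$validation),
        ph = metric_pair(pred$ph, split$validation$ph),
        po2_layer2 = metric_pair(pred$po2_layer2, split$validation$po2),
        po2_refined = metric_pair(pred$po2_refined, split$validation$po2)))
    if (!is.null(config$evaluate$cv) && config$evaluate$cv > 1) {
      cv <- kfold_cv(rbind_tables(split$train, split$validation),
                     k = config$evaluate$cv,
                     trainer = function(tr)
                       train_cascade(tr, cfg_ph = model$cfg_ph,
                                     cfg_o2 = model$cfg_o2,
                                     conditioning = model$conditioning),
                     seed = config$seed + 4L)
      evaluation$cv <- list(k = cv$k, aggregate = cv$aggregate)
    }
    jsonlite::write_json(evaluation, eval_path, auto_unbox = TRUE,
                         digits = NA)
    stage_log("evaluate", "hold-out pH MAE %.4g, refined pO2 MAE %.4g hPa",
              evaluation$holdout$ph$mae, evaluation$holdout$po2_refined$mae)
  } else {
    evaluation <- jsonlite::read_json(eval_path, simplifyVector = TRUE)
    stage_log("evaluate", "resumed: %s", eval_path)
  }

  # -- predict-image ----------------------------------------------------
  maps_dir <- file.path(out, "maps")
  image <- NULL
  if (force || !file.exists(file.path(maps_dir, "maps.json"))) {
    sc <- config$scene
    ph_field <- matrix(rep(seq(sc$ph[1], sc$ph[length(sc$ph)],
                               length.out = sc$width),
                           each = sc$height), sc$height, sc$width)
    scene <- generate_gradient_scene(sc$height, sc$width, ph_field,
                                     sc$po2, params = params, grid = grid,
                                     seed = config$seed + 5L)
    image <- predict_image(model, scene$cube)
    export_maps(image, maps_dir)
    stage_log("predict-image", "%dx%d scene -> %s (pH map MAE vs truth %.3g)",
              sc$height, sc$width, maps_dir,
              mae(as.numeric(image$ph_map), as.numeric(scene$truth$ph_map)))
  } else {
    stage_log("predict-image", "resumed: %s", maps_dir)
  }

  invisible(list(table = table, train = split$train,
                 validation = split$validation, model = model,
                 evaluation = evaluation, image = image))
}

#' Concatenate calibration tables sharing one wavelength axis
#' @param ... [calibration_table()]s.
#' @return A single [calibration_table()].
#' @export
rbind_tables <- function(...) {
  tabs <- list(...)
  wl <- table_wavelengths(tabs[[1]])
  for (t in tabs[-1]) {
    if (!isTRUE(all.equal(table_wavelengths(t), wl)))
      stop("rbind_tables: wavelength axes differ", call. = FALSE)
  }
  calibration_table(do.call(rbind, lapply(tabs, table_spectra)),
                    ph = unlist(lapply(tabs, `[[`, "ph")),
                    po2 = unlist(lapply(tabs, `[[`, "po2")),
                    wavelengths = wl,
                    provenance = unlist(lapply(tabs, `[[`, "provenance")))
}
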