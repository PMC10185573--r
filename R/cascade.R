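#' Gradient-boosted tree configuration
#'
#' Hyperparameters of one XGBoost regression layer. Defaults follow the
#' optimized settings of the two analyte layers: the pH layer uses
#' `gbt_config_ph()` = (250 trees, min_child_weight 3, depth 9, learning
#' rate 0.05); both oxygen layers use `gbt_config_o2()` = (250 trees,
#' min_child_weight 5, depth 7, learning rate 0.05).
#'
#' @param n_estimators Number of boosting rounds (>= 1).
#' @param min_child_weight Minimum hessian weight per leaf.
#' @param max_depth Maximum tree depth (>= 1).
#' @param learning_rate Shrinkage in (0, 1].
#' @param seed Integer seed for the booster.
#' @return Object of class `gbt_config`.
#' @export
gbt_config <- function(n_estimators = 250, min_child_weight = 3,
                       max_depth = 9, learning_rate = 0.05, seed = 1) {
  if (n_estimators < 1) stop("n_estimators must be >= 1", call. = FALSE)
  if (max_depth < 1) stop("max_depth must be >= 1", call. = FALSE)
  if (learning_rate <= 0 || learning_rate > 1)
    stop("learning_rate must lie in (0, 1]", call. = FALSE)
  structure(list(n_estimators = as.integer(n_estimators),
                 min_child_weight = min_child_weight,
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "gbt_config")
}

#' @rdname gbt_config
#' @export
gbt_config_ph <- function() gbt_config(250, 3, 9, 0.05)

#' @rdname gbt_config
#' @export
gbt_config_o2 <- function() gbt_config(250, 5, 7, 0.05)

# Fit one XGBoost regression layer; single-threaded for bit determinism.
# A single-valued target yields a constant predictor (with a warning
# at the cascade level).
fit_gbt <- function(x, y, cfg) {
  if (length(unique(y)) == 1L) {
    return(structure(list(constant = y[1]), class = "constant_regressor"))
  }
  params <- list(objective = "reg:squarederror",
                 max_depth = cfg$max_depth,
                 eta = cfg$learning_rate,
                 min_child_weight = cfg$min_child_weight,
                 nthread = 1,
                 seed = cfg$seed)
  xgboost::xgb.train(params = params,
                     data = xgboost::xgb.DMatrix(x, label = y),
                     nrounds = cfg$n_estimators, verbose = 0)
}

predict_gbt <- function(model, x) {
  if (inherits(model, "constant_regressor"))
    return(rep(model$constant, nrow(x)))
  stats::predict(model, xgboost::xgb.DMatrix(x))
}

#' Train the three-layer pH/O2 cascade
#'
#' The final model of the pipeline: three stacked gradient-boosted tree
#' regressors sharing one wavelength axis.
#' \enumerate{
#'   \item Layer 1 predicts pH from the raw absolute spectrum.
#'   \item Layer 2 predicts pO2 from the spectrum plus the *predicted* pH
#'     (conditional knowledge of the first analyte).
#'   \item Layer 3 refines the pO2 estimate from the spectrum, the
#'     predicted pH and layer 2's pO2 prediction --- one stacked
#'     refinement pass.
#' }
#' During training the conditioning features are, by default, out-of-fold
#' predictions from an internal `nfold_inner`-fold split (each training
#' row's predicted pH / pO2 comes from a booster that never saw that
#' row), which avoids the optimistic leakage of conditioning on a value
#' fitted to the row itself. `conditioning = "label"` instead conditions
#' on the true training labels (the predicted values are still used at
#' inference).
#'
#' @param train A [calibration_table()] with both labels present.
#' @param cfg_ph,cfg_o2 [gbt_config()] for layer 1 and for layers 2 and 3
#'   (the two oxygen layers share one configuration).
#' @param conditioning `"oof"` (default) or `"label"`; see Details.
#' @param nfold_inner Folds of the internal split used for out-of-fold
#'   conditioning (default 5).
#' @return Object of class `cascade_model`.
#' @export
train_cascade <- function(train,
                          cfg_ph = gbt_config_ph(),
                          cfg_o2 = gbt_config_o2(),
                          conditioning = c("oof", "label"),
                          nfold_inner = 5) {
  stopifnot(inherits(train, "calibration_table"), nrow(train) >= 1)
  conditioning <- match.arg(conditioning)
  x <- table_spectra(train)
  colnames(x) <- NULL
  ph <- train$ph; po2 <- train$po2
  if (length(unique(ph)) == 1L)
    warning("train_cascade: pH label is single-valued; ",
            "layer 1 is a constant predictor")
  if (length(unique(po2)) == 1L)
    warning("train_cascade: pO2 label is single-valued; ",
            "oxygen layers are constant predictors")
  n <- nrow(x)
  layer1 <- fit_gbt(x, ph, cfg_ph)

  oof_ok <- conditioning == "oof" && n >= 2 * nfold_inner
  ph_feat <- if (conditioning == "label") {
    ph
  } else if (oof_ok && length(unique(ph)) > 1L) {
    oof_predict(x, ph, cfg_ph, nfold_inner)
  } else {
    predict_gbt(layer1, x)
  }
  x2 <- cbind(x, ph_feat)
  layer2 <- fit_gbt(x2, po2, cfg_o2)
  if (oof_ok && length(unique(po2)) > 1L) {
    po2_feat <- oof_predict(x2, po2, cfg_o2, nfold_inner)
  } else {
    po2_feat <- predict_gbt(layer2, x2)
  }
  x3 <- cbind(x2, po2_feat)
  layer3 <- fit_gbt(x3, po2, cfg_o2)
  structure(list(layer1 = layer1, layer2 = layer2, layer3 = layer3,
                 wavelengths = table_wavelengths(train),
                 cfg_ph = cfg_ph, cfg_o2 = cfg_o2,
                 conditioning = conditioning,
                 n_train = n),
            class = "cascade_model")
}

# Out-of-fold predictions: deterministic contiguous fold assignment from
# the layer seed.
oof_predict <- function(x, y, cfg, nfold) {
  n <- nrow(x)
  assign_fold <- withr::with_seed(cfg$seed, sample(rep_len(seq_len(nfold), n)))
  out <- numeric(n)
  for (f in seq_len(nfold)) {
    hold <- which(assign_fold == f)
    m <- fit_gbt(x[-hold, , drop = FALSE], y[-hold], cfg)
    out[hold] <- predict_gbt(m, x[hold, , drop = FALSE])
  }
  out
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf(paste0("<cascade_model> 3 gradient-boosted layers ",
                     "(pH -> pO2 -> refined pO2), %d bands, %d training rows, ",
                     "%s conditioning\n"),
              length(x$wavelengths), x$n_train, x$conditioning))
  invisible(x)
}

#' Predict pH and pO2 for a batch of spectra
#'
#' Runs the three cascade layers in sequence. The `valid` flag applies
#' the sensor's dynamic-range rule: the pH sensing layer responds only
#' within pKa +/- 2, i.e. pH 5--9; predictions outside that range are
#' flagged physically unreliable (the oxygen values are still reported).
#' `po2_refined` is the model's reported oxygen estimate.
#'
#' @param model A [cascade_model()][train_cascade].
#' @param spectra Numeric matrix (rows = samples) or single spectrum
#'   vector; column count must match the model's wavelength axis.
#' @param ph_range Validity interval for the pH prediction.
#' @return Data frame `(ph, po2_layer2, po2_refined, valid)`, one row per
#'   input spectrum.
#' @export
predict_samples <- function(model, spectra, ph_range = c(5, 9)) {
  stopifnot(inherits(model, "cascade_model"))
  if (is.null(dim(spectra))) spectra <- matrix(spectra, nrow = 1)
  spectra <- as.matrix(spectra)
  colnames(spectra) <- NULL
  b <- length(model$wavelengths)
  if (ncol(spectra) != b)
    stop("predict_samples: spectra have ", ncol(spectra),
         " bands but the model expects ", b, call. = FALSE)
  ph <- predict_gbt(model$layer1, spectra)
  x2 <- cbind(spectra, ph)
  po2_l2 <- predict_gbt(model$layer2, x2)
  po2_l3 <- predict_gbt(model$layer3, cbind(x2, po2_l2))
  data.frame(ph = ph, po2_layer2 = po2_l2, po2_refined = po2_l3,
             valid = ph >= ph_range[1] & ph <= ph_range[2])
}
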