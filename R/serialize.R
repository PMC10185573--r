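#' Save / load a trained cascade as an artifact directory
#'
#' The on-disk format is a directory holding one file per booster layer
#' (`layer1.ubj`, `layer2.ubj`, `layer3.ubj`, XGBoost's portable UBJSON
#' model format; a constant layer is stored inside the JSON instead) plus
#' `cascade.json` with the wavelength axis, both layer configurations and
#' the conditioning mode.
#'
#' @param model A [cascade_model()][train_cascade].
#' @param dir Artifact directory (created if needed).
#' @return `save_cascade` returns `dir` invisibly; `load_cascade` returns
#'   the restored [cascade_model()][train_cascade].
#' @export
save_cascade <- function(model, dir) {
  stopifnot(inherits(model, "cascade_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(wavelengths = model$wavelengths,
               cfg_ph = unclass(model$cfg_ph),
               cfg_o2 = unclass(model$cfg_o2),
               conditioning = model$conditioning,
               n_train = model$n_train,
               constants = list())
  for (nm in c("layer1", "layer2", "layer3")) {
    layer <- model[[nm]]
    if (inherits(layer, "constant_regressor")) {
      meta$constants[[nm]] <- layer$constant
    } else {
      xgboost::xgb.save(layer, file.path(dir, paste0(nm, ".ubj")))
    }
  }
  jsonlite::write_json(meta, file.path(dir, "cascade.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(dir) {
  meta_path <- file.path(dir, "cascade.json")
  if (!file.exists(meta_path))
    stop("load_cascade: not a cascade artifact directory (no cascade.json): ",
         dir, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  get_layer <- function(nm) {
    if (!is.null(meta$constants[[nm]]))
      return(structure(list(constant = meta$constants[[nm]]),
                       class = "constant_regressor"))
    xgboost::xgb.load(file.path(dir, paste0(nm, ".ubj")))
  }
  structure(list(layer1 = get_layer("layer1"),
                 layer2 = get_layer("layer2"),
                 layer3 = get_layer("layer3"),
                 wavelengths = as.numeric(meta$wavelengths),
                 cfg_ph = do.call(gbt_config, meta$cfg_ph),
                 cfg_o2 = do.call(gbt_config, meta$cfg_o2),
                 conditioning = meta$conditioning,
                 n_train = meta$n_train),
            class = "cascade_model")
}
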