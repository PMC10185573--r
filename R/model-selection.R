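#' Regressor families screened during model identification
#' @return Character vector of the nine family names.
#' @export
selection_algorithms <- function() {
  c("linear", "lasso", "ridge", "logistic", "random_forest", "svm",
    "knn", "decision_tree", "xgboost")
}

# One fit/predict pair per family, each fitted on raw spectra for a single
# analyte. Returns list(predict = function(newx) ...). Seeded and
# single-threaded where the backend is stochastic or parallel.
fit_family <- function(name, x, y, seed = 1) {
  switch(name,
    linear = {
      fit <- stats::lm.fit(cbind(1, x), y)
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      list(predict = function(nx) drop(cbind(1, nx) %*% beta))
    },
    lasso = ,
    ridge = {
      alpha <- if (name == "lasso") 1 else 0
      fit <- withr::with_seed(seed,
        glmnet::cv.glmnet(x, y, alpha = alpha, nfolds = 5))
      list(predict = function(nx)
        drop(stats::predict(fit, nx, s = "lambda.min")))
    },
    logistic = {
      # The screening's "logistic regression" entry: a multinomial
      # classifier on integer-rounded targets, scored as a regressor.
      # Diagnostic only; expected to perform poorly on continuous targets.
      yr <- factor(round(y))
      fit <- withr::with_seed(seed,
        nnet::multinom(yr ~ ., data = data.frame(yr = yr, x),
                       MaxNWts = 100000, maxit = 50, trace = FALSE))
      list(predict = function(nx) {
        cls <- stats::predict(fit, newdata = data.frame(nx), type = "class")
        as.numeric(as.character(cls))
      })
    },
    random_forest = {
      fit <- ranger::ranger(x = x, y = y, num.trees = 100, seed = seed,
                            num.threads = 1)
      list(predict = function(nx)
        stats::predict(fit, data = nx, num.threads = 1)$predictions)
    },
    svm = {
      fit <- e1071::svm(x = x, y = y, type = "eps-regression",
                        kernel = "radial")
      list(predict = function(nx) as.numeric(stats::predict(fit, nx)))
    },
    knn = {
      fit <- caret::knnreg(x = x, y = y, k = 5)
      list(predict = function(nx) stats::predict(fit, nx))
    },
    decision_tree = {
      # unconstrained tree: memorizes duplicate-free training data exactly
      d <- data.frame(y = y, x)
      fit <- rpart::rpart(y ~ ., data = d, method = "anova",
                          control = rpart::rpart.control(
                            minsplit = 2, minbucket = 1, cp = 0,
                            maxdepth = 30, xval = 0, maxcompete = 0,
                            maxsurrogate = 0))
      list(predict = function(nx) stats::predict(fit, data.frame(nx)))
    },
    xgboost = {
      fit <- fit_gbt(x, y, gbt_config(n_estimators = 100,
                                      min_child_weight = 1,
                                      max_depth = 6, learning_rate = 0.3,
                                      seed = seed))
      list(predict = function(nx) predict_gbt(fit, nx))
    },
    stop("unknown algorithm: ", name, call. = FALSE)
  )
}

#' Screen regressor families for each analyte
#'
#' Fits each family independently per analyte on the raw training spectra
#' and scores training and validation MAE/RMSE, producing the comparison
#' table from which the gradient-boosted cascade was chosen. A family
#' that errors is recorded as a row of `NA`s (with a warning), never
#' fatally. The "logistic" family is a multinomial classifier on
#' integer-rounded targets, retained for diagnostic comparison only.
#'
#' @param train,validation [calibration_table()]s.
#' @param algorithms Subset of [selection_algorithms()].
#' @param analytes Targets to screen, among `"ph"` and `"po2"`.
#' @param seed Integer seed shared by all stochastic families.
#' @return Data frame of class `selection_report`: `(algorithm, analyte,
#'   train_mae, train_rmse, val_mae, val_rmse)`.
#' @export
model_selection <- function(train, validation,
                            algorithms = selection_algorithms(),
                            analytes = c("ph", "po2"),
                            seed = 1) {
  stopifnot(inherits(train, "calibration_table"), nrow(train) > 0,
            inherits(validation, "calibration_table"), nrow(validation) > 0)
  xtr <- table_spectra(train); xval <- table_spectra(validation)
  colnames(xtr) <- paste0("b", seq_len(ncol(xtr)))
  colnames(xval) <- colnames(xtr)
  rows <- list()
  for (an in analytes) {
    ytr <- train[[an]]; yval <- validation[[an]]
    for (alg in algorithms) {
      res <- tryCatch({
        m <- fit_family(alg, xtr, ytr, seed = seed)
        ptr <- m$predict(xtr); pval <- m$predict(xval)
        c(train_mae = mae(ptr, ytr), train_rmse = rmse(ptr, ytr),
          val_mae = mae(pval, yval), val_rmse = rmse(pval, yval))
      }, error = function(e) {
        warning("model_selection: ", alg, " (", an, ") failed: ",
                conditionMessage(e))
        c(train_mae = NA_real_, train_rmse = NA_real_,
          val_mae = NA_real_, val_rmse = NA_real_)
      })
      rows[[length(rows) + 1]] <- data.frame(
        algorithm = alg, analyte = an, t(res))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("selection_report", "data.frame")
  out
}

#' Hyperparameter sweep for a gradient-boosted layer
#'
#' Enumerates (grid mode) or randomly samples (random mode) candidate
#' [gbt_config()]s from per-hyperparameter candidate lists, fits each on
#' the training spectra for one analyte, and returns the configuration
#' with the lowest validation MAE (ties broken by validation RMSE, then
#' by first evaluation order). The full trace of every evaluated
#' configuration and its four metrics is returned.
#'
#' @param train,validation [calibration_table()]s.
#' @param space Named list of candidate vectors; names among
#'   `n_estimators`, `min_child_weight`, `max_depth`, `learning_rate`.
#' @param analyte `"ph"` or `"po2"`.
#' @param mode `"grid"` (exhaustive) or `"random"` (sample `budget`
#'   combinations without replacement).
#' @param budget Number of configurations to draw in random mode (>= 1).
#' @param seed Integer seed (sampling in random mode and the boosters).
#' @return `list(best = gbt_config, trace = data.frame)`.
#' @export
hpo_sweep <- function(train, validation, space,
                      analyte = c("ph", "po2"),
                      mode = c("grid", "random"),
                      budget = 10, seed = 1) {
  analyte <- match.arg(analyte); mode <- match.arg(mode)
  stopifnot(is.list(space), length(space) > 0,
            all(lengths(space) > 0))
  bad <- setdiff(names(space), c("n_estimators", "min_child_weight",
                                 "max_depth", "learning_rate"))
  if (length(bad) > 0)
    stop("hpo_sweep: unknown hyperparameters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (budget < 1) stop("hpo_sweep: budget must be >= 1", call. = FALSE)
  grid <- expand.grid(space, KEEP.OUT.ATTRS = FALSE)
  if (mode == "random") {
    pick <- withr::with_seed(seed,
      sample.int(nrow(grid), min(budget, nrow(grid))))
    grid <- grid[pick, , drop = FALSE]
  }
  xtr <- table_spectra(train); xval <- table_spectra(validation)
  colnames(xtr) <- NULL; colnames(xval) <- NULL
  ytr <- train[[analyte]]; yval <- validation[[analyte]]
  defaults <- if (analyte == "ph") gbt_config_ph() else gbt_config_o2()
  trace <- grid
  trace$train_mae <- trace$train_rmse <- NA_real_
  trace$val_mae <- trace$val_rmse <- NA_real_
  configs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- defaults
    for (nm in names(grid)) cfg[[nm]] <- grid[[nm]][i]
    cfg$seed <- as.integer(seed)
    configs[[i]] <- cfg
    m <- fit_gbt(xtr, ytr, cfg)
    ptr <- predict_gbt(m, xtr); pval <- predict_gbt(m, xval)
    trace$train_mae[i] <- mae(ptr, ytr)
    trace$train_rmse[i] <- rmse(ptr, ytr)
    trace$val_mae[i] <- mae(pval, yval)
    trace$val_rmse[i] <- rmse(pval, yval)
  }
  ord <- order(trace$val_mae, trace$val_rmse, seq_len(nrow(trace)))
  rownames(trace) <- NULL
  list(best = configs[[ord[1]]], trace = trace)
}
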