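#' Mean absolute error
#'
#' `MAE = sum(|y_i - x_i|) / N` between estimated values `y` and expected
#' target values `x`. Robust to outliers: large errors are not penalized
#' more than proportionally.
#'
#' @param estimates,targets Equal-length nonzero-length numeric vectors.
#' @return Scalar error in target units.
#' @examples
#' mae(c(2, 4), c(1, 1)) # 2
#' @export
mae <- function(estimates, targets) {
  check_metric_args(estimates, targets)
  mean(abs(estimates - targets))
}

#' Root mean square error
#'
#' `RMSE = sqrt(sum((y_i - x_i)^2) / N)`: the average magnitude of the
#' error, penalizing large deviations quadratically. Always >= the MAE of
#' the same residuals, with equality iff all absolute residuals are equal.
#'
#' @param estimates,targets Equal-length nonzero-length numeric vectors.
#' @return Scalar error in target units.
#' @examples
#' rmse(c(2, 4), c(1, 1)) # sqrt(5)
#' @export
rmse <- function(estimates, targets) {
  check_metric_args(estimates, targets)
  sqrt(mean((estimates - targets)^2))
}

check_metric_args <- function(estimates, targets) {
  if (!is.numeric(estimates) || !is.numeric(targets))
    stop("metric inputs must be numeric", call. = FALSE)
  if (length(estimates) != length(targets))
    stop("length mismatch: ", length(estimates), " estimates vs ",
         length(targets), " targets", call. = FALSE)
  if (length(estimates) == 0)
    stop("metric inputs must be nonempty", call. = FALSE)
  invisible(TRUE)
}

#' Both error metrics at once
#' @inheritParams mae
#' @return `list(mae, rmse, n)`.
#' @export
metric_pair <- function(estimates, targets) {
  list(mae = mae(estimates, targets), rmse = rmse(estimates, targets),
       n = length(targets))
}

#' k-fold cross-validation of a cascade trainer
#'
#' Randomly partitions the table into `k` folds of size `floor(N/k)` or
#' `ceiling(N/k)`; each fold serves once as validation while the trainer
#' is fitted on the remaining rows, so every row is validated exactly once
#' and never trains the model that scores it. Per fold, MAE and RMSE are
#' recorded for the three cascade outputs: pH (layer 1), pO2 first pass
#' (layer 2), pO2 refined (layer 3). The aggregate is the unweighted mean
#' (and sd) over folds.
#'
#' @param table A [calibration_table()] with `N >= k` rows.
#' @param k Number of folds (>= 2; default 10).
#' @param trainer Function `(calibration_table) -> model` where the model
#'   is accepted by [predict_samples()]. Defaults to [train_cascade()]
#'   with its default configurations.
#' @param seed Integer seed for the fold assignment.
#' @return Object of class `cv_report`: `list(k, folds, aggregate)` where
#'   `folds` is a data.frame `(fold, output, mae, rmse, n)` and
#'   `aggregate` a data.frame `(output, mae, rmse, mae_sd, rmse_sd)`.
#' @export
kfold_cv <- function(table, k = 10, trainer = NULL, seed = 1) {
  stopifnot(inherits(table, "calibration_table"))
  n <- nrow(table)
  if (k < 2) stop("kfold_cv: k must be >= 2", call. = FALSE)
  if (k > n) stop("kfold_cv: k (", k, ") exceeds the number of rows (", n, ")",
                  call. = FALSE)
  if (is.null(trainer)) trainer <- function(tr) train_cascade(tr)
  assign_fold <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  folds <- list()
  for (f in seq_len(k)) {
    val_idx <- which(assign_fold == f)
    model <- trainer(table[-val_idx, , drop = FALSE])
    val <- table[val_idx, , drop = FALSE]
    pred <- predict_samples(model, table_spectra(val))
    folds[[f]] <- data.frame(
      fold = f,
      output = c("ph", "po2_layer2", "po2_refined"),
      mae = c(mae(pred$ph, val$ph),
              mae(pred$po2_layer2, val$po2),
              mae(pred$po2_refined, val$po2)),
      rmse = c(rmse(pred$ph, val$ph),
               rmse(pred$po2_layer2, val$po2),
               rmse(pred$po2_refined, val$po2)),
      n = length(val_idx))
  }
  folds <- do.call(rbind, folds)
  agg <- do.call(rbind, lapply(split(folds, folds$output), function(d) {
    data.frame(output = d$output[1],
               mae = mean(d$mae), rmse = mean(d$rmse),
               mae_sd = stats::sd(d$mae), rmse_sd = stats::sd(d$rmse))
  }))
  rownames(agg) <- NULL
  structure(list(k = k, folds = folds, aggregate = agg, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold cross-validation\n", x$k))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-12s MAE %.4g +/- %.2g   RMSE %.4g +/- %.2g\n",
                agg$output[i], agg$mae[i], agg$mae_sd[i],
                agg$rmse[i], agg$rmse_sd[i]))
  }
  invisible(x)
}
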