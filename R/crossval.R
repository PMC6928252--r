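#' Leave-one-condition-out cross-validation with RMSE-vs-LV curves
#'
#' For each condition in turn: the standardization state and model are
#' computed on the remaining conditions only, the held-out slab is
#' standardized with that training state, predicted with 1..`max_lvs` latent
#' variables, and errors pooled over all held-out conditions, times and
#' variables. The headline RMSE is on the standardized scale (matching the
#' dimensionless RMSE axes used for component selection); raw-scale RMSE is
#' exported alongside.
#'
#' @param tensors a raw (pre-standardization) [tensor_pair()].
#' @param spec a [standardization_spec()] applied per fold (the default,
#'   leakage-free choice) or globally once when `restandardize = FALSE`.
#' @param max_lvs largest LV count to evaluate; capped at `i - 1` and at the
#'   unfolded dimensionality.
#' @param tol,max_iterations,seed fit settings (see [npls_fit()]); fold seeds
#'   are derived from `seed`, so the result is deterministic.
#' @param restandardize recompute standardization per training fold (default
#'   `TRUE`).
#' @return object of class `cv_result`: `rmse` and `rmse_raw` (one entry per
#'   LV count), per-fold measured/predicted slabs, `optimal_n_lvs`, and
#'   Pearson/Spearman correlations of pooled predictions at the optimum.
#' @export
loo_crossvalidate <- function(tensors, spec, max_lvs, tol = 1e-10,
                              max_iterations = 10000, seed = 1L,
                              restandardize = TRUE) {
  i <- dim(tensors$X)[1]
  if (i < 3) stopf("leave-one-condition-out needs >= 3 conditions, got %d", i)
  cap <- min(i - 1, prod(dim(tensors$X)[2:3]), prod(dim(tensors$Y)[2:3]))
  if (max_lvs > cap)
    stopf("max_lvs (%d) exceeds what %d conditions / the unfolded dims support (%d)",
          max_lvs, i, cap)
  conds <- dimnames(tensors$X)[[1]] %||% as.character(seq_len(i))

  global_state <- if (!restandardize) standardize_tensors(tensors, spec)$state else NULL

  folds <- list(); failed <- character(0)
  for (ci in seq_len(i)) {
    fold <- tryCatch({
      train <- tensor_pair(tensors$X[-ci, , , drop = FALSE],
                           tensors$Y[-ci, , , drop = FALSE])
      test <- tensor_pair(tensors$X[ci, , , drop = FALSE],
                          tensors$Y[ci, , , drop = FALSE])
      if (restandardize) {
        tr <- standardize_tensors(train, spec)
      } else {
        tr <- apply_state(train, global_state)
      }
      model <- suppressWarnings(
        npls_fit(tr$tensors, n_lvs = max_lvs, tol = tol,
                 max_iterations = max_iterations,
                 seed = derive_seed(seed, ci), on_exhausted = "truncate"))
      te <- apply_state(test, tr$state)
      meas_std <- te$tensors$Y
      n_avail <- length(model$lvs)
      # beyond the fold's numerical rank an extra LV contributes nothing:
      # predictions plateau at the last available count
      pred_std <- lapply(seq_len(max_lvs), function(n)
        predict(model, te$tensors$X, n_lvs_used = min(n, n_avail)))
      pred_raw <- lapply(pred_std, invert_predictions, state = te$state)
      list(condition = conds[ci], meas_std = meas_std, meas_raw = test$Y,
           pred_std = pred_std, pred_raw = pred_raw,
           # light training fingerprint: first-LV weights of the fold model
           w1 = if (length(model$lvs) > 0) model$lvs[[1]]$w else NULL)
    }, error = function(e) e)
    if (inherits(fold, "error")) {
      failed <- c(failed, conds[ci])
      warnf("fold '%s' failed and was skipped: %s", conds[ci], conditionMessage(fold))
    } else folds[[conds[ci]]] <- fold
  }
  if (length(folds) == 0) stopf("every cross-validation fold failed")

  pooled_sq <- function(scale) vapply(seq_len(max_lvs), function(n) {
    errs <- unlist(lapply(folds, function(f)
      as.vector(f[[paste0("pred_", scale)]][[n]] - f[[paste0("meas_", scale)]])))
    sqrt(mean(errs^2))
  }, numeric(1))
  rmse <- pooled_sq("std"); rmse_raw <- pooled_sq("raw")
  names(rmse) <- names(rmse_raw) <- seq_len(max_lvs)

  res <- structure(list(rmse = rmse, rmse_raw = rmse_raw, folds = folds,
                        max_lvs = max_lvs, seed = seed,
                        failed_folds = failed),
                   class = "cv_result")
  res$optimal_n_lvs <- select_optimal_lvs(res)
  corr <- prediction_correlations(res, n_lvs = res$optimal_n_lvs)
  res$pearson <- corr$pearson
  res$spearman <- corr$spearman
  res$per_condition <- corr$per_condition
  res
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>\n  RMSE (standardized):",
      paste(sprintf("LV%s=%.4g", names(x$rmse), x$rmse), collapse = " "), "\n")
  cat(sprintf("  optimal LVs: %d | Pearson R = %.3f | Spearman rho = %.3f\n",
              x$optimal_n_lvs, x$pearson, x$spearman))
  invisible(x)
}

#' Select the LV count minimizing the cross-validated RMSE
#'
#' Ties go to the smaller count (parsimony).
#' @param cv_result a `cv_result` (or a bare numeric RMSE curve).
#' @return integer LV count.
#' @export
select_optimal_lvs <- function(cv_result) {
  curve <- if (inherits(cv_result, "cv_result")) cv_result$rmse else cv_result
  if (length(curve) == 0) stopf("empty RMSE curve")
  as.integer(which.min(curve))
}

#' Correlations of cross-validated predictions with measurements
#'
#' Pearson and Spearman coefficients over all pooled held-out pairs at the
#' given LV count (the headline), plus per-condition coefficients.
#'
#' @param cv_result a `cv_result`.
#' @param n_lvs LV count at which to evaluate (default: the optimum).
#' @return list with `pearson`, `spearman` (pooled; `NA` with a warning when
#'   either vector has zero variance) and `per_condition` data.frame.
#' @export
prediction_correlations <- function(cv_result, n_lvs = NULL) {
  n <- n_lvs %||% cv_result$optimal_n_lvs
  pairs <- lapply(cv_result$folds, function(f)
    data.frame(condition = f$condition,
               measured = as.vector(f$meas_std),
               predicted = as.vector(f$pred_std[[n]])))
  pooled <- do.call(rbind, pairs)
  if (nrow(pooled) < 3) stopf("need >= 3 prediction/measurement pairs")
  safe_cor <- function(x, y, method) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warnf("zero variance in %s correlation input; reported as NA", method)
      return(NA_real_)
    }
    stats::cor(x, y, method = method)
  }
  per_condition <- do.call(rbind, lapply(pairs, function(p) data.frame(
    condition = p$condition[1],
    pearson = suppressWarnings(safe_cor(p$predicted, p$measured, "pearson")),
    spearman = suppressWarnings(safe_cor(p$predicted, p$measured, "spearman")))))
  rownames(per_condition) <- NULL
  list(pearson = safe_cor(pooled$predicted, pooled$measured, "pearson"),
       spearman = safe_cor(pooled$predicted, pooled$measured, "spearman"),
       per_condition = per_condition)
}
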