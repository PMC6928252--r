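#' Define a nested resampling scheme
#'
#' @param method `"jackknife"` (leave one replicate out per cell) or
#'   `"subsample"` (retain exactly one replicate per cell).
#' @param pairing `"unpaired"` draws X and Y replicates independently;
#'   `"paired"` selects/omits the same `pairing_id` in both blocks of each
#'   condition x time cell (requires pairing coverage).
#' @param n_iter number of resampling iterations (default 500).
#' @param seed master seed; per-iteration seeds are derived from it.
#' @param n_lvs LV count for every member model — fixed to the global-average
#'   model's optimum so members are comparable to it.
#' @return object of class `resampling_scheme`.
#' @export
resampling_scheme <- function(method = c("jackknife", "subsample"),
                              pairing = c("unpaired", "paired"),
                              n_iter = 500, seed = 1L, n_lvs) {
  structure(list(method = match.arg(method), pairing = match.arg(pairing),
                 n_iter = as.integer(n_iter), seed = as.integer(seed),
                 n_lvs = as.integer(n_lvs)),
            class = "resampling_scheme")
}

cell_split <- function(obs) {
  split(obs, paste(obs$block, obs$condition, obs$time, sep = "\r"), drop = TRUE)
}

draw_one <- function(dataset, method, paired, seed) {
  obs <- dataset$observations
  log_rows <- list()
  with_seed(seed, {
    if (!paired) {
      keep <- logical(nrow(obs))
      cells <- cell_split(obs)
      for (cl in names(cells)) {
        oc <- cells[[cl]]
        reps <- unique(oc$replicate_id)
        parts <- strsplit(cl, "\r", fixed = TRUE)[[1]]
        if (method == "jackknife") {
          if (length(reps) < 2)
            stopf("jackknife undefined: cell (block=%s, condition=%s, time=%s) has a single replicate",
                  parts[1], parts[2], parts[3])
          chosen <- sample(reps, 1)          # omitted
          kept <- setdiff(reps, chosen)
        } else {
          chosen <- sample(reps, 1)          # retained
          kept <- chosen
        }
        keep[obs$block == oc$block[1] & obs$condition == oc$condition[1] &
               obs$time == oc$time[1] & obs$replicate_id %in% kept] <- TRUE
        log_rows[[length(log_rows) + 1]] <- data.frame(
          block = parts[1], condition = parts[2], time = as.numeric(parts[3]),
          replicate_id = chosen,
          action = if (method == "jackknife") "omitted" else "retained",
          stringsAsFactors = FALSE)
      }
    } else {
      # couple the blocks: pick one pairing_id per condition x time cell
      keep <- logical(nrow(obs))
      ct <- unique(obs[, c("condition", "time")])
      for (r in seq_len(nrow(ct))) {
        sel <- obs$condition == ct$condition[r] & obs$time == ct$time[r]
        oc <- obs[sel, ]
        pair_sets <- lapply(split(oc, oc$block), function(o) {
          if (anyNA(o$pairing_id))
            stopf("paired resampling: cell (condition=%s, time=%s) block %s has replicates without pairing_id",
                  ct$condition[r], ct$time[r], o$block[1])
          unique(o$pairing_id)
        })
        shared <- Reduce(intersect, pair_sets)
        if (length(shared) == 0 || !all(vapply(pair_sets, setequal, logical(1), shared)))
          stopf("paired resampling: cell (condition=%s, time=%s) lacks full pairing coverage across blocks",
                ct$condition[r], ct$time[r])
        if (method == "jackknife") {
          if (length(shared) < 2)
            stopf("jackknife undefined: cell (condition=%s, time=%s) has a single paired replicate",
                  ct$condition[r], ct$time[r])
          chosen <- sample(shared, 1)
          keep[sel & !(obs$pairing_id %in% chosen)] <- TRUE
        } else {
          chosen <- sample(shared, 1)
          keep[sel & obs$pairing_id %in% chosen] <- TRUE
        }
        log_rows[[length(log_rows) + 1]] <- data.frame(
          block = "XY", condition = ct$condition[r], time = ct$time[r],
          replicate_id = chosen,
          action = if (method == "jackknife") "omitted" else "retained",
          stringsAsFactors = FALSE)
      }
    }
    out <- nested_dataset(obs[keep, , drop = FALSE],
                          time_unit = dataset$design$time_unit)
    attr(out, "draw_log") <- do.call(rbind, log_rows)
    out
  })
}

#' Jackknife draw: omit one replicate per condition x time cell
#'
#' One uniformly chosen replicate (animal) is removed from every cell,
#' together with all of its nested observations; every cell therefore needs
#' at least two replicates. Blocks are drawn independently unless `paired`.
#'
#' @param dataset a [nested_dataset()].
#' @param seed RNG seed.
#' @param paired couple the blocks through `pairing_id`.
#' @return the reduced [nested_dataset()], with the draw composition attached
#'   as attribute `"draw_log"`.
#' @export
jackknife_draw <- function(dataset, seed, paired = FALSE)
  draw_one(dataset, "jackknife", paired, seed)

#' Subsample draw: retain exactly one replicate per condition x time cell
#'
#' Builds an "n-of-one" dataset: per cell one uniformly chosen replicate
#' (animal) is kept with all of its observations.
#'
#' @inheritParams jackknife_draw
#' @return the n-of-one [nested_dataset()], with attribute `"draw_log"`.
#' @export
subsample_draw <- function(dataset, seed, paired = FALSE)
  draw_one(dataset, "subsample", paired, seed)

#' Align the signs of a model's latent variables to a reference
#'
#' Negating the scores and weights of an LV together is a degenerate
#' alternative solution; across resampled members this sign indeterminacy
#' shows up as symmetric bimodal weight distributions about zero. Each LV is
#' flipped to the dominant mode operationally: when the inner product of the
#' member's concatenated (w, q) with the reference's is negative, the whole
#' LV (w, q, t, u and the factored time weights) is negated. The inner
#' coefficients are recomputed from the flipped score matrices, which leaves
#' every prediction of the member bit-unchanged.
#'
#' @param model an `npls_model`.
#' @param reference an `npls_model` with the same LV count and grids.
#' @return the sign-aligned `npls_model`.
#' @export
align_signs_model <- function(model, reference) {
  if (length(model$lvs) != length(reference$lvs))
    stopf("reference has %d LVs, model has %d", length(reference$lvs), length(model$lvs))
  for (n in seq_along(model$lvs)) {
    lv <- model$lvs[[n]]; ref <- reference$lvs[[n]]
    s <- sum(lv$w * ref$w) + sum(lv$q * ref$q)
    if (s < 0) {
      for (f in c("w", "q", "t", "u", "w_time", "q_time"))
        lv[[f]] <- -lv[[f]]
      model$T[, n] <- -model$T[, n]
      model$U[, n] <- -model$U[, n]
    }
    # the (time, var) factorization split has its own sign ambiguity: flip
    # each pair jointly toward the reference (outer product unchanged), so
    # factored weights are comparable across members without the per-model
    # largest-entry convention masquerading as stability
    if (sum(lv$w_var * ref$w_var) < 0) {
      lv$w_var <- -lv$w_var; lv$w_time <- -lv$w_time
    }
    if (sum(lv$q_var * ref$q_var) < 0) {
      lv$q_var <- -lv$q_var; lv$q_time <- -lv$q_time
    }
    model$lvs[[n]] <- lv
  }
  if (length(model$lvs) > 0) {
    model$B_per_lv <- lapply(seq_along(model$lvs), function(n)
      inner_regression(model$T[, seq_len(n), drop = FALSE],
                       model$U[, seq_len(n), drop = FALSE]))
    model$B <- model$B_per_lv[[length(model$lvs)]]
  }
  model
}

#' Run a nested resampling ensemble
#'
#' For each iteration: draw (jackknife or subsample, paired or unpaired),
#' re-average, re-standardize (leniently: an n-of-one draw may make a slab
#' constant), refit with the fixed global LV count, sign-align to the global
#' reference, optionally leave-one-condition-out cross-validate, and record
#' weights and RMSE curves. Individual failures are logged and excluded;
#' more than `max_failure_fraction` failures aborts with diagnostics.
#'
#' @param dataset a [nested_dataset()] (for paired schemes, already
#'   restricted with [subset_design()] to the time points with pairing
#'   coverage).
#' @param scheme a [resampling_scheme()].
#' @param spec a [standardization_spec()]; the global reference uses it
#'   verbatim, members use a lenient copy.
#' @param reference optional global `npls_model`; fitted internally when
#'   `NULL`.
#' @param cv compute each member's LOO CV RMSE curve (default `TRUE`).
#' @param tol,max_iterations fit settings.
#' @param max_failure_fraction abort threshold (default 0.2).
#' @return object of class `resampling_ensemble`: member weight tables,
#'   member RMSE curves, the iteration log, the reference model, failure
#'   counts, and a robustness `summary` (see [summarize_robustness()]).
#' @export
run_ensemble <- function(dataset, scheme, spec, reference = NULL, cv = TRUE,
                         tol = 1e-10, max_iterations = 10000,
                         max_failure_fraction = 0.2) {
  tensors <- average_replicates(dataset)
  if (is.null(reference)) {
    std <- standardize_tensors(tensors, spec)
    reference <- npls_fit(std$tensors, n_lvs = scheme$n_lvs, tol = tol,
                          max_iterations = max_iterations,
                          seed = derive_seed(scheme$seed, 0))
  }
  lenient <- spec
  lenient$zero_variance <- "lenient"
  paired <- scheme$pairing == "paired"
  weights <- list(); curves <- list(); logs <- list(); errors <- character(0)
  for (it in seq_len(scheme$n_iter)) {
    res <- tryCatch(suppressWarnings({
      draw <- draw_one(dataset, scheme$method, paired, derive_seed(scheme$seed, it))
      tp <- average_replicates(draw)
      std <- standardize_tensors(tp, lenient)
      m <- npls_fit(std$tensors, n_lvs = scheme$n_lvs, tol = tol,
                    max_iterations = max_iterations,
                    seed = derive_seed(scheme$seed, scheme$n_iter + it))
      m <- align_signs_model(m, reference)
      wt <- weight_table(m)
      wt$iteration <- it
      curve <- if (cv) loo_crossvalidate(tp, lenient, max_lvs = scheme$n_lvs,
                                         tol = tol, max_iterations = max_iterations,
                                         seed = derive_seed(scheme$seed, 2L * scheme$n_iter + it))$rmse
               else NULL
      lg <- attr(draw, "draw_log"); lg$iteration <- it
      list(wt = wt, curve = curve, log = lg)
    }), error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("iteration %d: %s", it, conditionMessage(res)))
      next
    }
    weights[[length(weights) + 1]] <- res$wt
    if (!is.null(res$curve)) curves[[length(curves) + 1]] <- res$curve
    logs[[length(logs) + 1]] <- res$log
  }
  n_failed <- length(errors)
  if (n_failed > max_failure_fraction * scheme$n_iter)
    stopf("resampling aborted: %d/%d members failed. First failures:\n%s",
          n_failed, scheme$n_iter, paste(utils::head(errors, 3), collapse = "\n"))
  if (n_failed > 0)
    warnf("%d/%d resampling members failed and were excluded", n_failed, scheme$n_iter)
  ens <- structure(list(
    weights = do.call(rbind, weights),
    rmse_curves = if (length(curves) > 0) do.call(rbind, curves) else NULL,
    log = do.call(rbind, logs),
    scheme = scheme, reference = reference,
    n_members = length(weights), n_failed = n_failed,
    failures = errors
  ), class = "resampling_ensemble")
  ens$summary <- summarize_robustness(ens)
  ens
}

#' @export
print.resampling_ensemble <- function(x, ...) {
  cat(sprintf("<resampling_ensemble> %s/%s, %d members (%d failed), %d LVs\n",
              x$scheme$method, x$scheme$pairing, x$n_members, x$n_failed,
              x$scheme$n_lvs))
  print(x$summary$lv_summary)
  invisible(x)
}

#' Summarize per-weight robustness of a resampling ensemble
#'
#' Per weight coordinate (after sign alignment): ensemble mean, SD, and a
#' robust flag — the interval mean +/- SD must strictly exclude zero (an
#' error bar touching zero is fragile). When a [classify_significant()] mask
#' is supplied, the "retained" fraction is also reported: of the coordinates
#' significant under the randomization null, the fraction whose resampled
#' error bars exclude zero.
#'
#' @param ensemble a `resampling_ensemble`.
#' @param mask optional `significance_mask` on the same coordinates.
#' @return list with `table` (per-coordinate) and `lv_summary` (per block x
#'   LV x axis robust fractions, plus retained fractions when masked).
#' @export
summarize_robustness <- function(ensemble, mask = NULL) {
  w <- ensemble$weights
  if (is.null(w) || nrow(w) == 0) stopf("empty ensemble")
  key <- paste(w$block, w$lv, w$axis, w$index, sep = "\r")
  first <- !duplicated(key)
  tab <- w[first, c("block", "lv", "axis", "index", "label")]
  grp <- match(key, key[first])
  tab$mean <- as.vector(tapply(w$value, grp, mean)[as.character(seq_len(nrow(tab)))])
  sds <- as.vector(tapply(w$value, grp, stats::sd)[as.character(seq_len(nrow(tab)))])
  sds[is.na(sds)] <- 0
  tab$sd <- sds
  tab$robust <- abs(tab$mean) > tab$sd      # interval strictly excludes zero
  rownames(tab) <- NULL
  if (!is.null(mask)) {
    mkey <- paste(mask$block, mask$lv, mask$axis, mask$index, sep = "\r")
    pos <- match(paste(tab$block, tab$lv, tab$axis, tab$index, sep = "\r"), mkey)
    if (anyNA(pos)) stopf("significance mask does not cover all ensemble coordinates")
    tab$significant <- mask$significant[pos]
    tab$retained <- tab$significant & tab$robust
  }
  agg_by <- tab[, c("block", "lv", "axis")]
  lv_summary <- stats::aggregate(list(robust_fraction = tab$robust),
                                 by = agg_by, FUN = mean)
  if (!is.null(mask)) {
    ret <- stats::aggregate(
      list(n_significant = tab$significant, n_retained = tab$retained),
      by = agg_by, FUN = sum)
    lv_summary <- merge(lv_summary, ret, by = c("block", "lv", "axis"))
    lv_summary$retained_fraction <-
      ifelse(lv_summary$n_significant > 0,
             lv_summary$n_retained / lv_summary$n_significant, NA_real_)
  }
  lv_summary <- lv_summary[order(lv_summary$block, lv_summary$lv, lv_summary$axis), ]
  rownames(lv_summary) <- NULL
  list(table = tab, lv_summary = lv_summary)
}

#' Compare global and resampled-mean RMSE curves
#'
#' @param global_cv the global-average model's `cv_result`.
#' @param ensembles named list of `resampling_ensemble`s fitted with CV
#'   curves.
#' @return data.frame with one row per LV count: the global RMSE and each
#'   ensemble's member-mean RMSE.
#' @export
rmse_comparison <- function(global_cv, ensembles) {
  if (is.null(names(ensembles)) || any(names(ensembles) == ""))
    names(ensembles) <- vapply(ensembles, function(e) e$scheme$method, character(1))
  n <- unique(vapply(ensembles, function(e) {
    if (is.null(e$rmse_curves)) stopf("ensemble has no CV curves (run with cv = TRUE)")
    ncol(e$rmse_curves)
  }, integer(1)))
  if (length(n) != 1) stopf("ensembles have mismatched LV ranges")
  if (n > length(global_cv$rmse))
    stopf("ensemble LV range (%d) exceeds global CV curve (%d)", n, length(global_cv$rmse))
  out <- data.frame(lv = seq_len(n), global = unname(global_cv$rmse[seq_len(n)]))
  for (nm in names(ensembles))
    out[[nm]] <- colMeans(ensembles[[nm]]$rmse_curves)[seq_len(n)]
  out
}
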