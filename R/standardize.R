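#' Standardization recipe for a tensor pair
#'
#' Defines the preprocessing applied before decomposition, per block:
#' optional subtraction of a baseline time point (each entry minus the
#' same-condition, same-variable entry at the baseline time, so every
#' condition starts at zero) followed by variance scaling across the chosen
#' modes. Scaling "across mode 3" divides all entries sharing one measured
#' variable by that variable slab's scaling SD; "across mode 2" does the same
#' per time point. When both are selected, mode 3 is applied first, then
#' mode 2, and both factor sets are persisted.
#'
#' The scaling SD is the uncentered root-mean-square when `center = FALSE`
#' (the aortic-remodeling preset is uncentered) and the mean-centered SD when
#' `center = TRUE`.
#'
#' @param baseline_time named list (`X`, `Y`) of the baseline time value to
#'   subtract, or `NULL` entries for no subtraction.
#' @param scale_modes named list (`X`, `Y`) of character vectors, subsets of
#'   `c("mode2", "mode3")`.
#' @param center logical; use mean-centered SDs (and mean-center slabs) when
#'   scaling. Default `FALSE` (uncentered).
#' @param zero_variance `"strict"` errors on a zero-variance slab; `"lenient"`
#'   records a factor of 1 (used inside resampling loops where an n-of-one
#'   draw can make a slab constant).
#' @return object of class `standardization_spec`.
#' @seealso [spec_baseline_mode3()], [spec_modes23()]
#' @export
standardization_spec <- function(baseline_time = list(X = NULL, Y = NULL),
                                 scale_modes = list(X = "mode3", Y = "mode3"),
                                 center = FALSE,
                                 zero_variance = c("strict", "lenient")) {
  zero_variance <- match.arg(zero_variance)
  for (b in c("X", "Y")) {
    bad <- setdiff(scale_modes[[b]], c("mode2", "mode3"))
    if (length(bad) > 0) stopf("unknown scaling mode(s): %s", paste(bad, collapse = ", "))
  }
  structure(list(baseline_time = baseline_time, scale_modes = scale_modes,
                 center = center, zero_variance = zero_variance),
            class = "standardization_spec")
}

#' Preset: baseline subtraction + mode-3 scaling (in vivo remodeling studies)
#'
#' Day-0 values are subtracted per condition and variable, then each measured
#' variable is scaled by its uncentered slab SD. This is the recipe for
#' differential-change designs where baseline differences between conditions
#' should not be modeled.
#' @param baseline baseline time value (default 0).
#' @return a [standardization_spec()].
#' @export
spec_baseline_mode3 <- function(baseline = 0) {
  standardization_spec(baseline_time = list(X = baseline, Y = baseline),
                       scale_modes = list(X = "mode3", Y = "mode3"))
}

#' Preset: no transformation (already-commensurate data)
#'
#' Useful for synthetic data generated on a common unit scale, where scaling
#' would distort the planted structure.
#' @return a [standardization_spec()].
#' @export
spec_identity <- function() {
  standardization_spec(scale_modes = list(X = character(0), Y = character(0)))
}

#' Preset: variance scaling across modes 2 and 3, no baseline subtraction
#' @param center use mean-centered SDs (default FALSE, uncentered).
#' @return a [standardization_spec()].
#' @export
spec_modes23 <- function(center = FALSE) {
  standardization_spec(scale_modes = list(X = c("mode2", "mode3"),
                                          Y = c("mode2", "mode3")),
                       center = center)
}

scaling_sd <- function(x, center) {
  if (center) stats::sd(x) else sqrt(mean(x^2))
}

std_one_block <- function(arr, baseline_time, modes, center, zero_variance,
                          frozen = NULL) {
  state <- list(baseline_time = baseline_time, baseline = NULL,
                mode3 = NULL, mode2 = NULL, center = center)
  if (!is.null(baseline_time)) {
    tpos <- match(as.character(baseline_time), dimnames(arr)[[2]])
    if (is.na(tpos)) stopf("baseline time %s absent from time grid", baseline_time)
    base <- arr[, tpos, , drop = FALSE]               # i x 1 x k
    state$baseline <- base[, 1, , drop = TRUE]
    if (is.null(dim(state$baseline)))                 # keep i x k shape
      state$baseline <- matrix(state$baseline, dim(arr)[1], dim(arr)[3],
                               dimnames = dimnames(arr)[c(1, 3)])
    arr <- sweep(arr, c(1, 3), state$baseline, "-")
  }
  slab_factor <- function(values, label) {
    s <- scaling_sd(values, center)
    if (s == 0 || !is.finite(s)) {
      if (zero_variance == "strict")
        stopf("zero-variance slab '%s' under strict standardization", label)
      warnf("zero-variance slab '%s'; scale factor set to 1", label)
      s <- 1
    }
    s
  }
  if (is.null(frozen)) {
    if ("mode3" %in% modes) {
      k <- dim(arr)[3]
      state$mode3 <- vapply(seq_len(k), function(v)
        slab_factor(arr[, , v], dimnames(arr)[[3]][v]), numeric(1))
      names(state$mode3) <- dimnames(arr)[[3]]
      arr <- sweep(arr, 3, state$mode3, "/")
    }
    if ("mode2" %in% modes) {
      j <- dim(arr)[2]
      state$mode2 <- vapply(seq_len(j), function(t)
        slab_factor(arr[, t, ], dimnames(arr)[[2]][t]), numeric(1))
      names(state$mode2) <- dimnames(arr)[[2]]
      arr <- sweep(arr, 2, state$mode2, "/")
    }
  } else {
    if (!is.null(frozen$mode3)) {
      if (length(frozen$mode3) != dim(arr)[3]) stopf("mode-3 factor/grid mismatch")
      state$mode3 <- frozen$mode3
      arr <- sweep(arr, 3, frozen$mode3, "/")
    }
    if (!is.null(frozen$mode2)) {
      if (length(frozen$mode2) != dim(arr)[2]) stopf("mode-2 factor/grid mismatch")
      state$mode2 <- frozen$mode2
      arr <- sweep(arr, 2, frozen$mode2, "/")
    }
  }
  list(arr = arr, state = state)
}

#' Standardize a tensor pair
#'
#' Applies the spec (baseline subtraction first, then scaling) and returns
#' both the transformed tensors and a `standardization_state` holding every
#' factor and baseline actually applied, so held-out data can be standardized
#' consistently and predictions inverted back to measurement scale.
#'
#' @param tensors a [tensor_pair()].
#' @param spec a [standardization_spec()].
#' @return list with `tensors` (standardized [tensor_pair()]) and `state`.
#' @export
standardize_tensors <- function(tensors, spec) {
  out <- list(); state <- list()
  for (b in c("X", "Y")) {
    r <- std_one_block(tensors[[b]], spec$baseline_time[[b]],
                       spec$scale_modes[[b]], spec$center, spec$zero_variance)
    out[[b]] <- r$arr; state[[b]] <- r$state
  }
  state$spec <- spec
  class(state) <- "standardization_state"
  list(tensors = tensor_pair(out$X, out$Y), state = state)
}

#' Standardize new data with a frozen state
#'
#' Applies the same arithmetic as [standardize_tensors()] but with the
#' training state's scale factors; the baseline value subtracted is the new
#' tensor's own baseline-time entry (baseline subtraction is within-condition
#' by definition, so no training information is needed or leaked). The
#' realized per-condition baselines are recorded in the returned state so
#' predictions for these conditions can be inverted.
#'
#' @param tensors a [tensor_pair()] on the raw scale (a held-out condition
#'   slice, say).
#' @param state a `standardization_state` from [standardize_tensors()].
#' @return list with `tensors` and the realized `state` for this data.
#' @export
apply_state <- function(tensors, state) {
  out <- list(); new_state <- list()
  for (b in c("X", "Y")) {
    if (is.null(tensors[[b]])) next
    st <- state[[b]]
    if (!is.null(st$mode3) && length(st$mode3) != dim(tensors[[b]])[3])
      stopf("block %s: variable grid mismatch with state", b)
    r <- std_one_block(tensors[[b]], st$baseline_time, NULL, st$center,
                       "lenient", frozen = st)
    out[[b]] <- r$arr
    new_state[[b]] <- r$state
  }
  new_state$spec <- state$spec
  class(new_state) <- "standardization_state"
  list(tensors = tensor_pair(out$X %||% NULL, out$Y %||% NULL), state = new_state)
}

#' Invert standardized predictions back to measurement scale
#'
#' Multiplies scale factors back (mode 2, then mode 3 — the reverse of the
#' forward order) and re-adds the per-condition baseline recorded in `state`.
#'
#' @param Y_hat_std predicted dependent array on the standardized scale,
#'   conditions x times x variables, with condition dimnames matching the
#'   baselines recorded in `state`.
#' @param state the realized `standardization_state` for the predicted
#'   conditions (from [standardize_tensors()] or [apply_state()]).
#' @return array on the raw measurement scale.
#' @export
invert_predictions <- function(Y_hat_std, state) {
  st <- state$Y
  arr <- Y_hat_std
  if (!is.null(st$mode2)) {
    if (length(st$mode2) != dim(arr)[2]) stopf("mode-2 factor/shape mismatch")
    arr <- sweep(arr, 2, st$mode2, "*")
  }
  if (!is.null(st$mode3)) {
    if (length(st$mode3) != dim(arr)[3]) stopf("mode-3 factor/shape mismatch")
    arr <- sweep(arr, 3, st$mode3, "*")
  }
  if (!is.null(st$baseline)) {
    base <- st$baseline
    conds <- dimnames(arr)[[1]]
    if (!is.null(conds) && !is.null(rownames(base))) {
      if (!all(conds %in% rownames(base)))
        stopf("state lacks baselines for condition(s): %s",
              paste(setdiff(conds, rownames(base)), collapse = ", "))
      base <- base[conds, , drop = FALSE]
    }
    if (nrow(base) != dim(arr)[1]) stopf("baseline/shape mismatch")
    arr <- sweep(arr, c(1, 3), base, "+")
  }
  arr
}
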