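#' Shuffle raw tensors within mode 1
#'
#' Within each condition slab of each block, all (time x variable) entries are
#' permuted uniformly at random; the multiset of values per slab is conserved
#' exactly and condition identity is untouched. The two blocks are shuffled
#' independently. With `preserve_rows = TRUE`, whole time rows are permuted
#' instead of individual entries (a stricter null that keeps within-time
#' variable profiles intact).
#'
#' @param tensors a raw (pre-standardization) [tensor_pair()].
#' @param seed RNG seed.
#' @param preserve_rows permute whole time rows instead of entries.
#' @return shuffled [tensor_pair()].
#' @export
shuffle_within_mode1 <- function(tensors, seed, preserve_rows = FALSE) {
  with_seed(seed, {
    out <- lapply(tensors[c("X", "Y")], function(arr) {
      for (ci in seq_len(dim(arr)[1])) {
        slab <- arr[ci, , , drop = TRUE]
        if (is.null(dim(slab)))
          slab <- matrix(slab, dim(arr)[2], dim(arr)[3])
        if (preserve_rows) {
          slab <- slab[sample(nrow(slab)), , drop = FALSE]
        } else {
          slab[] <- sample(as.vector(slab))
        }
        arr[ci, , ] <- slab
      }
      arr
    })
    tensor_pair(out$X, out$Y)
  })
}

#' Build a randomization null distribution for model weights
#'
#' Repeatedly shuffles the raw global-average tensors within mode 1,
#' re-standardizes, refits with the global model's LV count, sign-aligns each
#' null model to the global reference, and accumulates the per-coordinate
#' mean and SD of every weight. Weights of the actual model lying outside one
#' null SD of the null mean are the candidates worth interpreting.
#'
#' @param tensors raw (pre-standardization) global-average [tensor_pair()].
#' @param spec a [standardization_spec()]; shuffled data are re-standardized
#'   with a lenient copy of it (a shuffle cannot be allowed to abort the loop
#'   on a degenerate slab).
#' @param n_lvs LV count of the global-average model.
#' @param n_iter shuffling iterations (default 500).
#' @param seed master seed; iteration seeds are derived from it.
#' @param reference optional fitted global `npls_model` used as the sign
#'   reference; fitted internally from `tensors` + `spec` when `NULL`.
#' @param tol,max_iterations fit settings.
#' @return object of class `null_distribution`: a coordinate table with
#'   `null_mean` and `null_sd`, plus `n_iter`, `n_failed`, `seed` and the
#'   reference model.
#' @export
build_null <- function(tensors, spec, n_lvs, n_iter = 500, seed = 1L,
                       reference = NULL, tol = 1e-10, max_iterations = 10000) {
  if (is.null(reference)) {
    std <- standardize_tensors(tensors, spec)
    reference <- npls_fit(std$tensors, n_lvs = n_lvs, tol = tol,
                          max_iterations = max_iterations,
                          seed = derive_seed(seed, 0))
  }
  lenient <- spec
  lenient$zero_variance <- "lenient"
  acc <- NULL; acc_sq <- NULL; n_ok <- 0L; n_failed <- 0L
  for (it in seq_len(n_iter)) {
    res <- tryCatch({
      shuffled <- shuffle_within_mode1(tensors, seed = derive_seed(seed, it))
      std <- suppressWarnings(standardize_tensors(shuffled, lenient))
      m <- suppressWarnings(npls_fit(std$tensors, n_lvs = n_lvs, tol = tol,
                                     max_iterations = max_iterations,
                                     seed = derive_seed(seed, n_iter + it)))
      weight_table(align_signs_model(m, reference))
    }, error = function(e) e)
    if (inherits(res, "error")) { n_failed <- n_failed + 1L; next }
    if (is.null(acc)) {
      acc <- res; acc$value <- 0; acc_sq <- 0
    }
    acc$value <- acc$value + res$value
    acc_sq <- acc_sq + res$value^2
    n_ok <- n_ok + 1L
  }
  if (n_ok == 0) stopf("every null iteration failed")
  tab <- acc[, c("block", "lv", "axis", "index", "label")]
  tab$null_mean <- acc$value / n_ok
  var_hat <- pmax(acc_sq / n_ok - tab$null_mean^2, 0)
  tab$null_sd <- if (n_ok > 1) sqrt(var_hat * n_ok / (n_ok - 1)) else 0
  structure(list(table = tab, n_iter = n_iter, n_ok = n_ok,
                 n_failed = n_failed, seed = seed, reference = reference),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d/%d iterations ok (%d failed), %d coordinates\n",
              x$n_ok, x$n_iter, x$n_failed, nrow(x$table)))
  invisible(x)
}

#' Classify globally significant weights against a null distribution
#'
#' A weight is significant when it exceeds one standard deviation from the
#' null mean: `|weight - null_mean| > null_sd` (strict; the boundary is not
#' significant).
#'
#' @param model the global `npls_model` (or a [weight_table()] data.frame).
#' @param null a `null_distribution` from [build_null()].
#' @return data.frame (class `significance_mask`) with the model weight, null
#'   mean/SD and a `significant` flag per coordinate.
#' @export
classify_significant <- function(model, null) {
  wt <- if (is.data.frame(model)) model else weight_table(model)
  key <- function(d) paste(d$block, d$lv, d$axis, d$index, sep = "\r")
  nt <- null$table
  pos <- match(key(wt), key(nt))
  if (anyNA(pos))
    stopf("null distribution lacks %d coordinate(s) present in the model",
          sum(is.na(pos)))
  out <- wt
  out$null_mean <- nt$null_mean[pos]
  out$null_sd <- nt$null_sd[pos]
  out$significant <- abs(out$value - out$null_mean) > out$null_sd
  class(out) <- c("significance_mask", class(out))
  out
}
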