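#' Unfold a 3-way array into a matrix (mode-1 matricization)
#'
#' Rows index mode 1 (conditions); columns enumerate (time, variable) pairs
#' with the variable index running fastest, i.e. column `(j-1)*k + v` holds
#' time `j`, variable `v`. Every weight reshape in the package uses this same
#' fixed order; [refold3()] is its exact inverse.
#'
#' @param a dense 3-way array.
#' @return matrix of shape `i x (j*k)` with column labels `"time|variable"`.
#' @export
unfold3 <- function(a) {
  if (length(dim(a)) != 3) stopf("unfold3 expects a 3-way array")
  d <- dim(a); dn <- dimnames(a)
  m <- aperm(a, c(1, 3, 2))           # i x k x j: k fastest within each j
  dim(m) <- c(d[1], d[2] * d[3])
  if (!is.null(dn)) {
    rownames(m) <- dn[[1]]
    colnames(m) <- as.vector(t(outer(dn[[2]], dn[[3]], paste, sep = "|")))
  }
  m
}

#' Refold a mode-1 unfolded matrix back into a 3-way array
#'
#' @param m matrix of shape `i x (j*k)` in [unfold3()] column order.
#' @param j,k time and variable dimensions.
#' @param dimnames optional dimnames for the result.
#' @return array of shape `i x j x k`.
#' @export
refold3 <- function(m, j, k, dimnames = NULL) {
  if (ncol(m) != j * k) stopf("refold3: %d columns cannot refold to %d x %d", ncol(m), j, k)
  a <- array(m, dim = c(nrow(m), k, j))
  a <- aperm(a, c(1, 3, 2))
  dimnames(a) <- dimnames
  a
}

#' Least-squares inner regression between score matrices
#'
#' Coefficients `B = (T'T)^{-1} T'U` mapping independent condition scores to
#' dependent condition scores; a scalar when one latent variable is in play.
#'
#' @param T_matrix,U_matrix score matrices with one column per latent variable.
#' @return coefficient matrix (n x n).
#' @export
inner_regression <- function(T_matrix, U_matrix) {
  T_matrix <- as.matrix(T_matrix); U_matrix <- as.matrix(U_matrix)
  g <- crossprod(T_matrix)
  if (qr(g)$rank < ncol(T_matrix))
    stopf("rank-deficient score matrix: degenerate draw or duplicate latent variables")
  solve(g, crossprod(T_matrix, U_matrix))
}

rank1_factorize <- function(vec, j, k, time_labels = NULL, var_labels = NULL) {
  W <- matrix(vec, nrow = k, ncol = j)          # variable fastest -> k x j
  W <- t(W)                                     # j x k
  sv <- svd(W)
  w_time <- sv$u[, 1] * sv$d[1]
  w_var <- sv$v[, 1]
  s <- sign(w_var[which.max(abs(w_var))])
  if (s == 0) s <- 1
  w_var <- w_var * s; w_time <- w_time * s
  names(w_time) <- time_labels; names(w_var) <- var_labels
  list(time = w_time, var = w_var,
       residual = 1 - sv$d[1]^2 / sum(sv$d^2))
}

extract_lv <- function(Xm, Ym, tol, max_iterations) {
  if (all(Xm == 0) || all(Ym == 0)) stopf("no variance left to model")
  sv <- svd(Ym, nu = 1, nv = 0)
  u <- sv$u[, 1] * sv$d[1]                      # principal component 1 of Y residual
  t_prev <- stats::rnorm(nrow(Xm))              # random t initialization
  converged <- FALSE; iterations <- 0L
  w <- q <- t_cur <- NULL
  for (it in seq_len(max_iterations)) {
    iterations <- it
    w <- drop(crossprod(Xm, u)); w <- w / sqrt(sum(w^2))
    t_cur <- drop(Xm %*% w)
    q <- drop(crossprod(Ym, t_cur)); q <- q / sqrt(sum(q^2))
    u <- drop(Ym %*% q)
    if (abs(sqrt(sum(t_cur^2)) - sqrt(sum(t_prev^2))) <= tol) {
      converged <- TRUE
      break
    }
    t_prev <- t_cur
  }
  b <- sum(t_cur * u) / sum(t_cur^2)
  list(t = t_cur, u = u, w = w, q = q, b = b,
       iterations = iterations, converged = converged)
}

#' Fit a tri-linear partial least squares regression model
#'
#' Iteratively extracts latent variables (LVs) linking the independent array
#' `X` (conditions x times x variables) to the dependent array `Y`. Each LV is
#' found by alternating back-projections on the mode-1 unfolded residuals:
#' `w = X'u`, `t = Xw`, `q = Y't`, `u = Yq`, with `w` and `q` renormalized to
#' unit length each pass, iterated from a PCA-initialized `u` (and a random
#' `t`) until the change in the magnitude of `t` falls to `tol`. After
#' convergence the combined weights are factorized into time and variable
#' parts by the leading singular vectors of their `j x k` reshape (the rank-1
#' factorization residual is reported, not hidden), the inner coefficient
#' `b = (t't)^{-1} t'u` is computed, and both blocks are deflated: `X` by
#' `t w'` and `Y` by the predicted contribution `b t q'`. The full inner
#' coefficient matrix `B = (T'T)^{-1} T'U` is accumulated per LV count.
#'
#' @param tensors a standardized [tensor_pair()].
#' @param n_lvs number of latent variables to extract (0 allowed).
#' @param tol convergence threshold on the change in `||t||` (default 1e-10).
#' @param max_iterations iteration guard per LV (default 10000); hitting it
#'   warns and flags the LV as unconverged.
#' @param seed seed for the random `t` initialization; fits are bit-for-bit
#'   reproducible under the same seed.
#' @param on_exhausted what to do when a block's residual variance is
#'   numerically exhausted (relative Frobenius norm below 1e-9) before all
#'   requested LVs are extracted: `"error"` (default) or `"truncate"`, which
#'   stops early with a warning and returns the LVs supported by the data.
#'   Cross-validation uses `"truncate"` so noiseless low-rank data produce a
#'   plateauing RMSE curve instead of a failure.
#' @return object of class `npls_model`: per-LV scores (`t`, `u`), combined
#'   weights (`w`, `q`), factored time/variable weights, inner coefficients
#'   (`b` per LV, `B` per LV count), residual arrays after final deflation,
#'   residual norms per step, and the fit settings.
#' @export
npls_fit <- function(tensors, n_lvs, tol = 1e-10, max_iterations = 10000,
                     seed = 1L, on_exhausted = c("error", "truncate")) {
  on_exhausted <- match.arg(on_exhausted)
  X <- tensors$X; Y <- tensors$Y
  dx <- dim(X); dy <- dim(Y)
  dnx <- dimnames(X); dny <- dimnames(Y)
  if (dx[1] != dy[1]) stopf("X and Y must share the condition dimension")
  if (n_lvs < 0) stopf("n_lvs must be >= 0")
  Xm <- unfold3(X); Ym <- unfold3(Y)
  x_norm0 <- fnorm(Xm); y_norm0 <- fnorm(Ym)
  lvs <- list()
  Tm <- matrix(0, dx[1], 0); Um <- matrix(0, dx[1], 0)
  resid_norms <- data.frame(lv = integer(0), X = numeric(0), Y = numeric(0))
  with_seed(seed, {
    for (n in seq_len(n_lvs)) {
      exhausted <- fnorm(Xm) <= 1e-9 * x_norm0 || fnorm(Ym) <= 1e-9 * y_norm0
      if (exhausted) {
        if (on_exhausted == "error") stopf("no variance left to model (LV %d)", n)
        warnf("residual variance exhausted after %d LV(s); truncating", n - 1L)
        break
      }
      lv <- extract_lv(Xm, Ym, tol, max_iterations)
      if (!lv$converged)
        warnf("LV %d hit max_iterations (%d) without converging", n, max_iterations)
      fw <- rank1_factorize(lv$w, dx[2], dx[3], dnx[[2]], dnx[[3]])
      fq <- rank1_factorize(lv$q, dy[2], dy[3], dny[[2]], dny[[3]])
      lv$w_time <- fw$time; lv$w_var <- fw$var; lv$w_rank1_residual <- fw$residual
      lv$q_time <- fq$time; lv$q_var <- fq$var; lv$q_rank1_residual <- fq$residual
      lv$index <- n
      Xm <- Xm - tcrossprod(lv$t, lv$w)
      Ym <- Ym - lv$b * tcrossprod(lv$t, lv$q)
      Tm <- cbind(Tm, lv$t); Um <- cbind(Um, lv$u)
      resid_norms <- rbind(resid_norms,
                           data.frame(lv = n, X = fnorm(Xm), Y = fnorm(Ym)))
      lvs[[n]] <- lv
    }
  })
  n_fit <- length(lvs)
  B_per_lv <- lapply(seq_len(n_fit), function(n)
    inner_regression(Tm[, seq_len(n), drop = FALSE], Um[, seq_len(n), drop = FALSE]))
  structure(list(
    lvs = lvs, T = Tm, U = Um,
    B = if (n_fit > 0) B_per_lv[[n_fit]] else matrix(0, 0, 0),
    B_per_lv = B_per_lv,
    X_residual = refold3(Xm, dx[2], dx[3], dnx),
    Y_residual = refold3(Ym, dy[2], dy[3], dny),
    residual_norms = resid_norms,
    initial_norms = c(X = x_norm0, Y = y_norm0),
    dims = list(X = dx, Y = dy), dimnames = list(X = dnx, Y = dny),
    settings = list(n_lvs = n_lvs, tol = tol,
                    max_iterations = max_iterations, seed = seed)
  ), class = "npls_model")
}

#' @export
print.npls_model <- function(x, ...) {
  cat(sprintf("<npls_model> %d LV(s), X %s -> Y %s\n", length(x$lvs),
              paste(x$dims$X, collapse = "x"), paste(x$dims$Y, collapse = "x")))
  if (length(x$lvs) > 0) {
    ev <- x$residual_norms
    cat(sprintf("  residual X: %s | residual Y: %s\n",
                paste(signif(ev$X / x$initial_norms["X"], 3), collapse = " "),
                paste(signif(ev$Y / x$initial_norms["Y"], 3), collapse = " ")))
  }
  invisible(x)
}

#' Predict the dependent array for new conditions
#'
#' New condition scores are obtained by sequentially projecting the new
#' unfolded residuals onto each LV's `w` (with matching deflation), then
#' `Y_hat = sum_n b_n t_new_n q_n'`, refolded to conditions x times x
#' variables. The per-LV inner coefficients `b_n` are used (a diagonal inner
#' relation) because that is the form consistent with the per-LV deflation
#' `Y_res - b t q'`: with it, predicting the training conditions with all LVs
#' reproduces `Y` minus the final residual exactly. The full inner matrix `B`
#' is still reported on the model for audit.
#'
#' @param object an `npls_model`.
#' @param X_new independent array for the new conditions, standardized with
#'   the model's training state; time/variable grids must match training.
#' @param n_lvs_used number of leading LVs to use (default: all fitted).
#' @param ... unused.
#' @return predicted dependent array (standardized scale).
#' @export
predict.npls_model <- function(object, X_new, n_lvs_used = NULL, ...) {
  n_avail <- length(object$lvs)
  n_use <- n_lvs_used %||% n_avail
  if (n_use > n_avail) stopf("n_lvs_used (%d) exceeds fitted LV count (%d)", n_use, n_avail)
  dx <- object$dims$X; dy <- object$dims$Y
  if (!all(dim(X_new)[2:3] == dx[2:3]))
    stopf("X_new grid %s does not match training grid %s",
          paste(dim(X_new)[2:3], collapse = "x"), paste(dx[2:3], collapse = "x"))
  Xm <- unfold3(X_new)
  i_new <- nrow(Xm)
  out_dimnames <- list(dimnames(X_new)[[1]], object$dimnames$Y[[2]], object$dimnames$Y[[3]])
  if (n_use == 0)
    return(array(0, dim = c(i_new, dy[2], dy[3]), dimnames = out_dimnames))
  T_new <- matrix(0, i_new, n_use)
  for (n in seq_len(n_use)) {
    w <- object$lvs[[n]]$w
    T_new[, n] <- Xm %*% w
    Xm <- Xm - tcrossprod(T_new[, n], w)
  }
  Q <- vapply(object$lvs[seq_len(n_use)], `[[`, numeric(dy[2] * dy[3]), "q")
  b <- vapply(object$lvs[seq_len(n_use)], `[[`, numeric(1), "b")
  Yh <- T_new %*% (b * t(Q))
  refold3(Yh, dy[2], dy[3], out_dimnames)
}

#' Long-format table of a model's weight coordinates
#'
#' One row per weight coordinate: combined weights (`axis = "combined"`, one
#' coordinate per time x variable pair) and the factored time and variable
#' weights (`axis = "time"` / `"var"`), for both blocks and every LV. This is
#' the coordinate system shared by the null-model significance masks and the
#' resampling robustness summaries.
#'
#' @param model an `npls_model`.
#' @return data.frame with columns `block`, `lv`, `axis`, `index`, `label`,
#'   `value`.
#' @export
weight_table <- function(model) {
  rows <- list()
  for (lv in model$lvs) {
    n <- lv$index
    comb_lab_x <- colnames(unfold3(model$X_residual)) %||% as.character(seq_along(lv$w))
    comb_lab_y <- colnames(unfold3(model$Y_residual)) %||% as.character(seq_along(lv$q))
    rows[[length(rows) + 1]] <- data.frame(
      block = "X", lv = n, axis = "combined", index = seq_along(lv$w),
      label = comb_lab_x, value = lv$w, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      block = "X", lv = n, axis = "time", index = seq_along(lv$w_time),
      label = names(lv$w_time) %||% as.character(seq_along(lv$w_time)),
      value = unname(lv$w_time), stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      block = "X", lv = n, axis = "var", index = seq_along(lv$w_var),
      label = names(lv$w_var) %||% as.character(seq_along(lv$w_var)),
      value = unname(lv$w_var), stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      block = "Y", lv = n, axis = "combined", index = seq_along(lv$q),
      label = comb_lab_y, value = lv$q, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      block = "Y", lv = n, axis = "time", index = seq_along(lv$q_time),
      label = names(lv$q_time) %||% as.character(seq_along(lv$q_time)),
      value = unname(lv$q_time), stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      block = "Y", lv = n, axis = "var", index = seq_along(lv$q_var),
      label = names(lv$q_var) %||% as.character(seq_along(lv$q_var)),
      value = unname(lv$q_var), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a fitted model to JSON
#'
#' Scores, weights, inner coefficients, settings and convergence diagnostics;
#' round-trips through `jsonlite` for audit and the command-line pipeline.
#' @param model an `npls_model`.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  payload <- list(
    settings = model$settings,
    dims = model$dims,
    scores_t = model$T, scores_u = model$U,
    B = model$B,
    lvs = lapply(model$lvs, function(lv)
      lv[c("index", "w", "q", "w_time", "w_var", "q_time", "q_var",
           "b", "iterations", "converged", "w_rank1_residual", "q_rank1_residual")]),
    residual_norms = model$residual_norms
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
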