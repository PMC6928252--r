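# Independent oracles and fixture builders. Everything here is coded from
# first principles, separately from the package internals it checks.

# random dense tensor pair with dimnames
random_tensor_pair <- function(i, j, k, l, m, seed) {
  set.seed(seed)
  X <- array(rnorm(i * j * k), dim = c(i, j, k),
             dimnames = list(sprintf("c%d", 1:i), as.character(seq_len(j) - 1),
                             sprintf("x%d", 1:k)))
  Y <- array(rnorm(i * l * m), dim = c(i, l, m),
             dimnames = list(sprintf("c%d", 1:i), as.character(seq_len(l) - 1),
                             sprintf("y%d", 1:m)))
  tensor_pair(X, Y)
}

# long-format toy dataset: full crossing, n_reps replicates everywhere,
# values drawn iid so the nesting machinery can be exercised directly
toy_dataset <- function(conditions = c("a", "b"), times = c(0, 1),
                        x_vars = c("x1", "x2"), y_vars = c("y1", "y2"),
                        n_reps = 3, seed = 1, paired = FALSE,
                        y_times = times, n_reps_Y = n_reps) {
  set.seed(seed)
  mk <- function(block, tms, vars, nr) {
    g <- expand.grid(condition = conditions, time = tms, variable = vars,
                     replicate_id = sprintf("r%d", seq_len(nr)),
                     stringsAsFactors = FALSE)
    g$block <- block
    g$pairing_id <- if (paired) sub("r", "p", g$replicate_id) else NA_character_
    g$value <- rnorm(nrow(g))
    g
  }
  nested_dataset(rbind(mk("X", times, x_vars, n_reps),
                       mk("Y", y_times, y_vars, n_reps_Y)))
}

# dominant eigenvector of the unfolded cross-covariance operator X'YY'X;
# the one-LV score direction is X applied to it
oracle_lv1_scores <- function(X_unf, Y_unf) {
  M <- t(X_unf) %*% Y_unf %*% t(Y_unf) %*% X_unf
  w <- eigen(M, symmetric = TRUE)$vectors[, 1]
  drop(X_unf %*% w)
}

# straightforward two-block bilinear PLS on plain matrices, written
# independently of the package: PC1-initialized u, unit-norm w and q,
# prediction-based Y deflation
oracle_bilinear_pls <- function(Xm, Ym, n_lvs, tol = 1e-10, max_iter = 10000) {
  scores_t <- NULL; scores_u <- NULL
  Ws <- NULL; Qs <- NULL; bs <- numeric(0)
  for (n in seq_len(n_lvs)) {
    sv <- svd(Ym)
    u <- sv$u[, 1] * sv$d[1]
    norm_prev <- -1
    for (it in seq_len(max_iter)) {
      w <- drop(t(Xm) %*% u); w <- w / sqrt(sum(w^2))
      t_ <- drop(Xm %*% w)
      q <- drop(t(Ym) %*% t_); q <- q / sqrt(sum(q^2))
      u <- drop(Ym %*% q)
      if (abs(sqrt(sum(t_^2)) - norm_prev) <= tol) break
      norm_prev <- sqrt(sum(t_^2))
    }
    b <- sum(t_ * u) / sum(t_^2)
    Xm <- Xm - outer(t_, w)
    Ym <- Ym - b * outer(t_, q)
    scores_t <- cbind(scores_t, t_); scores_u <- cbind(scores_u, u)
    Ws <- cbind(Ws, w); Qs <- cbind(Qs, q); bs <- c(bs, b)
  }
  list(T = scores_t, U = scores_u, W = Ws, Q = Qs, b = bs)
}

abs_cos <- function(a, b) abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))

fnorm_test <- function(a) sqrt(sum(a^2))
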