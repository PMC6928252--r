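test_that("unfold3 orders columns variable-fastest and refolds exactly", {
  a <- array(seq_len(3 * 4 * 5), dim = c(3, 4, 5))
  m <- unfold3(a)
  expect_equal(dim(m), c(3, 20))
  # index-arithmetic oracle: column (j-1)*k + v holds time j, variable v
  for (j in 1:4) for (v in 1:5)
    expect_equal(m[, (j - 1) * 5 + v], a[, j, v])
  expect_equal(refold3(m, 4, 5), a)
  # row 1 is the flattened first condition slab (variable fastest)
  a2 <- array(rnorm(8), dim = c(2, 2, 2))
  expect_equal(unfold3(a2)[1, ], as.vector(t(a2[1, , ])))
})

test_that("single-LV extraction matches the cross-covariance eigendecomposition", {
  tp <- random_tensor_pair(4, 3, 3, 4, 2, seed = 10)
  m <- npls_fit(tp, n_lvs = 1, seed = 3)
  t_oracle <- oracle_lv1_scores(unfold3(tp$X), unfold3(tp$Y))
  expect_gt(abs_cos(m$lvs[[1]]$t, t_oracle), 1 - 1e-6)
})

test_that("planted rank-1 structure is recovered and forced support is found", {
  set.seed(20)
  t0 <- rnorm(5); a <- rnorm(3); b <- rnorm(4); cc <- rnorm(2); d <- rnorm(3)
  X <- outer(outer(t0, a), b)
  Y <- outer(outer(t0, cc), d)
  m <- npls_fit(tensor_pair(X, Y), n_lvs = 1, seed = 1)
  expect_gt(abs_cos(m$lvs[[1]]$w_var, b), 1 - 1e-8)
  expect_gt(abs_cos(m$lvs[[1]]$q_var, d), 1 - 1e-8)
  expect_lt(m$lvs[[1]]$w_rank1_residual, 1e-12)

  # Y with a single nonzero column: q is that unit basis vector up to sign
  Y2 <- array(0, dim = c(5, 2, 3))
  Y2[, 2, 3] <- rnorm(5)
  m2 <- npls_fit(tensor_pair(X, Y2), n_lvs = 1, seed = 1)
  q <- m2$lvs[[1]]$q
  expect_equal(abs(q[(2 - 1) * 3 + 3]), 1, tolerance = 1e-10)  # time 2, var 3
  expect_lt(sum(q^2) - max(q^2), 1e-16)
})

test_that("inner_regression matches an independent least-squares oracle", {
  expect_equal(drop(inner_regression(cbind(1:4), cbind(1:4))), 1)
  expect_equal(drop(inner_regression(cbind(1:4), cbind(2 * 1:4))), 2)
  set.seed(30)
  T_ <- matrix(rnorm(12), 6, 2); U_ <- matrix(rnorm(12), 6, 2)
  expect_equal(inner_regression(T_, U_), qr.solve(T_, U_),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(inner_regression(cbind(1:4, 2 * (1:4)), cbind(1:4, 1:4)),
               "rank-deficient")
})

test_that("deflation is exact on rank-1 data and never increases residual norms", {
  set.seed(40)
  X <- outer(outer(rnorm(4), rnorm(3)), rnorm(3))
  Y <- outer(outer(rnorm(4), rnorm(2)), rnorm(2))
  m <- npls_fit(tensor_pair(X, Y), n_lvs = 1, seed = 1)
  expect_lt(fnorm_test(m$X_residual), 1e-8 * fnorm_test(X))
  # property sweep: residual norms non-increasing in both blocks
  for (seed in 1:20) {
    tp <- random_tensor_pair(4, 2, 3, 4, 2, seed = 100 + seed)
    m <- npls_fit(tp, n_lvs = 3, seed = seed)
    rn <- m$residual_norms
    expect_true(all(diff(c(m$initial_norms["X"], rn$X)) <= 1e-10))
    expect_true(all(diff(c(m$initial_norms["Y"], rn$Y)) <= 1e-10))
  }
  # orthogonal planted 2-LV structure: second extraction recovers component 2
  set.seed(41)
  Qs <- qr.Q(qr(matrix(rnorm(5 * 2), 5, 2)))
  At <- qr.Q(qr(matrix(rnorm(3 * 2), 3, 2)))
  Av <- qr.Q(qr(matrix(rnorm(4 * 2), 4, 2)))
  Bt <- qr.Q(qr(matrix(rnorm(3 * 2), 3, 2)))
  Bv <- qr.Q(qr(matrix(rnorm(4 * 2), 4, 2)))
  X2 <- 3 * outer(outer(Qs[, 1], At[, 1]), Av[, 1]) +
        1 * outer(outer(Qs[, 2], At[, 2]), Av[, 2])
  Y2 <- 3 * outer(outer(Qs[, 1], Bt[, 1]), Bv[, 1]) +
        1 * outer(outer(Qs[, 2], Bt[, 2]), Bv[, 2])
  m2 <- npls_fit(tensor_pair(X2, Y2), n_lvs = 2, seed = 2)
  expect_gt(abs_cos(m2$lvs[[2]]$w_var, Av[, 2]), 1 - 1e-6)
})

test_that("fit handles n_lvs = 0, is deterministic, and warns on iteration cap", {
  tp <- random_tensor_pair(4, 2, 2, 4, 2, seed = 50)
  m0 <- npls_fit(tp, n_lvs = 0, seed = 1)
  expect_length(m0$lvs, 0)
  expect_equal(m0$X_residual, tp$X)
  m1 <- npls_fit(tp, n_lvs = 2, seed = 9)
  m2 <- npls_fit(tp, n_lvs = 2, seed = 9)
  expect_identical(m1$T, m2$T)
  expect_identical(m1$lvs[[2]]$w, m2$lvs[[2]]$w)
  expect_warning(npls_fit(tp, n_lvs = 1, seed = 1, max_iterations = 1),
                 "max_iterations")
})

test_that("predict: self-consistency, linearity, and a hand-computed one-LV probe", {
  tp <- random_tensor_pair(5, 3, 2, 5, 2, seed = 60)
  m <- npls_fit(tp, n_lvs = 4, seed = 4)
  # training predictions reproduce Y minus the final residual
  expect_lt(max(abs(predict(m, tp$X) - (tp$Y - m$Y_residual))), 1e-8)
  zero <- tp$X; zero[] <- 0
  expect_true(all(predict(m, zero) == 0))
  # one-LV model on a one-condition probe: Y_hat = b * t_new * q'
  m1 <- npls_fit(tp, n_lvs = 1, seed = 4)
  probe <- tp$X[2, , , drop = FALSE]
  t_new <- drop(unfold3(probe) %*% m1$lvs[[1]]$w)
  by_hand <- refold3(matrix(drop(m1$B) * t_new * m1$lvs[[1]]$q, nrow = 1), 5, 2)
  expect_equal(unname(predict(m1, probe, 1)), unname(by_hand), tolerance = 1e-10)
  expect_error(predict(m, tp$X, n_lvs_used = 9), "exceeds")
  expect_error(predict(m, tp$X[, 1:2, , drop = FALSE]), "does not match")
})

test_that("whole-LV sign flips leave predictions unchanged", {
  tp <- random_tensor_pair(5, 2, 3, 5, 2, seed = 70)
  m <- npls_fit(tp, n_lvs = 3, seed = 1)
  flipped <- m
  n <- 2
  for (f in c("w", "q", "t", "u", "w_time", "q_time"))
    flipped$lvs[[n]][[f]] <- -flipped$lvs[[n]][[f]]
  flipped$T[, n] <- -flipped$T[, n]
  flipped$U[, n] <- -flipped$U[, n]
  flipped$B_per_lv <- lapply(seq_along(flipped$lvs), function(nn)
    inner_regression(flipped$T[, seq_len(nn), drop = FALSE],
                     flipped$U[, seq_len(nn), drop = FALSE]))
  expect_equal(predict(flipped, tp$X, 3), predict(m, tp$X, 3), tolerance = 1e-12)
})

test_that("degenerate time dimension reduces to bilinear PLS", {
  set.seed(80)
  Xm <- matrix(rnorm(6 * 4), 6, 4)
  Ym <- matrix(rnorm(6 * 3), 6, 3)
  tp <- tensor_pair(array(Xm, dim = c(6, 1, 4)), array(Ym, dim = c(6, 1, 3)))
  m <- npls_fit(tp, n_lvs = 2, seed = 1)
  ref <- oracle_bilinear_pls(Xm, Ym, n_lvs = 2)
  for (n in 1:2) {
    expect_lt(max(abs(abs(m$T[, n]) - abs(ref$T[, n]))), 1e-8)
    expect_lt(max(abs(abs(m$lvs[[n]]$w) - abs(ref$W[, n]))), 1e-8)
  }
})

test_that("model JSON serialization round-trips the key quantities", {
  tp <- random_tensor_pair(4, 2, 2, 4, 2, seed = 90)
  m <- npls_fit(tp, n_lvs = 2, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$lvs$b, vapply(m$lvs, `[[`, numeric(1), "b"))
  expect_equal(unname(as.matrix(back$scores_t)), unname(m$T))
})
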