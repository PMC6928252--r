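test_that("jackknife draws omit exactly one whole replicate per cell, uniformly", {
  ds <- toy_dataset(conditions = "a", times = 0, x_vars = "x1", y_vars = "y1",
                    n_reps = 3, seed = 1)
  omitted <- character(6000)
  for (s in 1:6000) {
    draw <- jackknife_draw(ds, seed = s)
    lg <- attr(draw, "draw_log")
    omitted[s] <- lg$replicate_id[lg$block == "X"]
    # remaining replicates are intact
    left <- draw$observations[draw$observations$block == "X", ]
    expect_equal(sort(unique(left$replicate_id)),
                 setdiff(c("r1", "r2", "r3"), omitted[s]))
  }
  freq <- table(omitted) / 6000
  p <- 1 / 3
  expect_true(all(abs(freq - p) < 3 * sqrt(p * (1 - p) / 6000)))
  # single-replicate cells make the jackknife undefined
  ds1 <- toy_dataset(n_reps = 1)
  expect_error(jackknife_draw(ds1, seed = 1), "jackknife undefined")
})

test_that("subsample draws keep one nested replicate per cell and are reproducible", {
  ds <- toy_dataset(n_reps = 3, seed = 2)
  d1 <- subsample_draw(ds, seed = 10)
  expect_true(all(d1$replicate_counts$n_replicates == 1))
  # nesting: the draw is a union of whole replicates per cell
  obs <- d1$observations
  per_cell <- tapply(obs$variable, paste(obs$block, obs$condition, obs$time,
                                         obs$replicate_id), length)
  expect_true(all(per_cell == 2))          # both variables of the block
  d2 <- subsample_draw(ds, seed = 10)
  expect_identical(d1$observations, d2$observations)
  # n-of-one identity
  ds1 <- toy_dataset(n_reps = 1, seed = 3)
  expect_equal(subsample_draw(ds1, seed = 1)$observations$value,
               ds1$observations$value)
})

test_that("paired draws couple the blocks; unpaired draws do not", {
  ds <- toy_dataset(n_reps = 2, seed = 4, paired = TRUE)
  for (s in 1:10) {
    draw <- subsample_draw(ds, seed = s, paired = TRUE)
    obs <- draw$observations
    for (cl in split(obs, paste(obs$condition, obs$time)))
      expect_length(unique(cl$pairing_id), 1)  # same animal in X and Y
  }
  # unpaired: X and Y selections agree only at chance rate
  match_frac <- mean(vapply(1:200, function(s) {
    obs <- subsample_draw(ds, seed = 1000 + s)$observations
    cl <- obs[obs$condition == "a" & obs$time == 0, ]
    length(unique(cl$pairing_id)) == 1
  }, logical(1)))
  expect_gt(match_frac, 0.5 - 3 * sqrt(0.25 / 200))
  expect_lt(match_frac, 0.5 + 3 * sqrt(0.25 / 200))
  # missing pairing coverage is an error
  ds_np <- toy_dataset(n_reps = 2, seed = 5, paired = FALSE)
  expect_error(subsample_draw(ds_np, seed = 1, paired = TRUE),
               "without pairing_id")
})

test_that("exhaustive 2-replicate jackknife means recover the global average", {
  ds <- toy_dataset(conditions = "a", times = 0, x_vars = "x1", y_vars = "y1",
                    n_reps = 2, seed = 6)
  tp <- average_replicates(ds)
  # both leave-one-out configurations, enumerated by hand
  vals <- ds$observations$value[ds$observations$block == "X"]
  jk_means <- c(vals[1], vals[2])          # leaving out r2 then r1
  expect_equal(mean(jk_means), unname(tp$X[1, 1, 1]))
})

test_that("sign alignment collapses constructed flips and preserves predictions", {
  tp <- random_tensor_pair(5, 3, 3, 5, 2, seed = 400)
  m <- npls_fit(tp, n_lvs = 3, seed = 1)
  flipped <- m
  for (f in c("w", "q", "t", "u", "w_time", "q_time"))
    flipped$lvs[[2]][[f]] <- -flipped$lvs[[2]][[f]]
  flipped$T[, 2] <- -flipped$T[, 2]; flipped$U[, 2] <- -flipped$U[, 2]
  aligned <- align_signs_model(flipped, m)
  expect_equal(aligned$lvs[[2]]$w, m$lvs[[2]]$w)
  expect_equal(aligned$T, m$T)
  expect_equal(predict(aligned, tp$X, 3), predict(m, tp$X, 3), tolerance = 1e-10)

  # bimodality-collapse oracle: noisy copies with random wholesale flips
  set.seed(7)
  members <- lapply(1:40, function(it) {
    mm <- m
    for (n in 1:3) {
      noise_w <- rnorm(length(mm$lvs[[n]]$w), 0, 0.05)
      noise_q <- rnorm(length(mm$lvs[[n]]$q), 0, 0.05)
      mm$lvs[[n]]$w <- mm$lvs[[n]]$w + noise_w
      mm$lvs[[n]]$q <- mm$lvs[[n]]$q + noise_q
      if (runif(1) < 0.5) {
        mm$lvs[[n]]$w <- -mm$lvs[[n]]$w; mm$lvs[[n]]$q <- -mm$lvs[[n]]$q
      }
    }
    mm
  })
  sd_pre <- sd(vapply(members, function(mm) mm$lvs[[1]]$w[1], numeric(1)))
  aligned_members <- lapply(members, align_signs_model, reference = m)
  sd_post <- sd(vapply(aligned_members, function(mm) mm$lvs[[1]]$w[1], numeric(1)))
  # brute-force per-coordinate fold of the bimodal distribution
  vals <- vapply(members, function(mm) mm$lvs[[1]]$w[1], numeric(1))
  folded_sd <- sd(vals * ifelse(vapply(members, function(mm)
    sum(mm$lvs[[1]]$w * m$lvs[[1]]$w) + sum(mm$lvs[[1]]$q * m$lvs[[1]]$q),
    numeric(1)) < 0, -1, 1))
  expect_lt(sd_post, sd_pre)
  expect_equal(sd_post, folded_sd)
})

test_that("run_ensemble is reproducible and its summaries follow the boundary rules", {
  ds <- toy_dataset(conditions = c("a", "b", "c", "d"), n_reps = 3, seed = 8)
  sch <- resampling_scheme("jackknife", n_iter = 2, seed = 42, n_lvs = 2)
  e1 <- run_ensemble(ds, sch, spec_modes23(), cv = FALSE)
  e2 <- run_ensemble(ds, sch, spec_modes23(), cv = FALSE)
  expect_equal(e1$n_members, 2)
  expect_identical(e1$weights, e2$weights)
  expect_identical(e1$log, e2$log)

  # robustness boundary rules on a synthetic summary
  fake <- structure(list(weights = data.frame(
    block = "Y", lv = 1, axis = "var", index = rep(1:3, each = 2),
    label = rep(c("m", "f", "edge"), each = 2),
    value = c(0.5, 1.5, -0.2, 0.8, 0.0, 1.0),   # mean 1/sd .707; mean .3/sd .707; mean .5/sd .707
    iteration = rep(1:2, 3))), class = "resampling_ensemble")
  tab <- summarize_robustness(fake)$table
  expect_equal(tab$mean, c(1.0, 0.3, 0.5))
  expect_equal(tab$robust, c(TRUE, FALSE, FALSE))
  # exact textbook cases: mean 1.0 sd 0.5 robust; mean .3 sd .5 fragile;
  # mean .5 sd .5 fragile (touching zero)
  direct <- data.frame(mean = c(1, 0.3, 0.5), sd = c(0.5, 0.5, 0.5))
  expect_equal(abs(direct$mean) > direct$sd, c(TRUE, FALSE, FALSE))
})

test_that("high member-failure rates abort with diagnostics", {
  ds <- toy_dataset(n_reps = 1, seed = 9)   # jackknife impossible everywhere
  sch <- resampling_scheme("jackknife", n_iter = 5, seed = 1, n_lvs = 1)
  expect_error(run_ensemble(ds, sch, spec_modes23(), cv = FALSE),
               "resampling aborted")
})

test_that("rmse_comparison lines up curves and degenerates correctly", {
  pm <- planted_model(i = 4, n_lvs_true = 2, replicate_noise_sd = 0,
                      measurement_noise_sd = 0, n_reps_X = 2, n_reps_Y = 2)
  gen <- generate_planted(pm)
  tp <- average_replicates(gen$dataset)
  cv <- suppressWarnings(loo_crossvalidate(tp, spec_identity(), max_lvs = 2, seed = 1))
  sch <- function(m) resampling_scheme(m, n_iter = 3, seed = 5, n_lvs = 2)
  ens <- list(
    jackknife = run_ensemble(gen$dataset, sch("jackknife"), spec_identity(), cv = TRUE),
    subsample = run_ensemble(gen$dataset, sch("subsample"), spec_identity(), cv = TRUE))
  cmp <- rmse_comparison(cv, ens)
  # zero replicate variance: all three curves identical
  expect_equal(cmp$jackknife, cmp$global, tolerance = 1e-10)
  expect_equal(cmp$subsample, cmp$global, tolerance = 1e-10)
  expect_error(rmse_comparison(list(rmse = cv$rmse[1]), ens), "exceeds")
})
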