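test_that("read_long_csv validates, counts replicates, and honours schema maps", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(region = "ATA", day = 0, marker = "eln", grp = "X",
                   animal = sprintf("m%d", 1:4), value = c(1, 3, 5, 7))
  write.csv(df, path, row.names = FALSE)
  schema <- list(condition = "region", time = "day", variable = "marker",
                 block = "grp", replicate_id = "animal")
  ds <- read_long_csv(path, schema = schema)
  expect_s3_class(ds, "nested_dataset")
  expect_equal(ds$replicate_counts$n_replicates, 4)

  # one nested replicate carrying three variables is one animal, not three
  df3 <- expand.grid(condition = "c", time = 0, variable = c("v1", "v2", "v3"),
                     block = "X", replicate_id = "m1", stringsAsFactors = FALSE)
  df3$value <- 1:3
  ds3 <- nested_dataset(df3)
  expect_equal(ds3$replicate_counts$n_replicates, 1)
  expect_equal(nrow(ds3$observations), 3)

  # missing required column
  expect_error(nested_dataset(df3[, setdiff(names(df3), "value")]),
               "missing required column")
  # duplicate (cell, replicate, variable) rows
  expect_error(nested_dataset(rbind(df3, df3[1, ])), "duplicate")
  # a replicate under two pairing ids in one cell
  bad <- rbind(
    data.frame(condition = "c", time = 0, variable = c("v1", "v2"), block = "X",
               replicate_id = "m1", pairing_id = c("p1", "p2"), value = 1:2))
  expect_error(nested_dataset(bad), "pairing_id collision")
})

test_that("average_replicates matches a brute-force groupby-mean oracle", {
  ds <- toy_dataset(n_reps = 3, seed = 42)
  tp <- average_replicates(ds)
  expect_equal(dim(tp$X), c(2, 2, 2))
  obs <- ds$observations
  for (b in c("X", "Y")) {
    arr <- tp[[b]]
    o <- obs[obs$block == b, ]
    for (ci in dimnames(arr)[[1]]) for (ti in dimnames(arr)[[2]])
      for (vi in dimnames(arr)[[3]]) {
        sel <- o$condition == ci & o$time == as.numeric(ti) & o$variable == vi
        expect_equal(arr[ci, ti, vi], mean(o$value[sel]))
      }
  }
  # single-replicate cells reproduce the raw values
  ds1 <- toy_dataset(n_reps = 1, seed = 7)
  tp1 <- average_replicates(ds1)
  o1 <- ds1$observations
  expect_equal(as.numeric(tp1$X["a", "0", "x1"]),
               o1$value[o1$block == "X" & o1$condition == "a" &
                        o1$time == 0 & o1$variable == "x1"])
})

test_that("simulate_replicates_from_summary is normal, nested, deterministic", {
  tab <- data.frame(block = "X", condition = "c", time = 0,
                    variable = c("v1", "v2"), mean = c(10, -4), sd = c(2, 0))
  big <- simulate_replicates_from_summary(tab, n_sim = 10000, seed = 11)
  v1 <- big$observations$value[big$observations$variable == "v1"]
  v2 <- big$observations$value[big$observations$variable == "v2"]
  expect_lt(abs(mean(v1) - 10), 3 * 2 / sqrt(10000))
  expect_lt(abs(sd(v1) - 2) / 2, 0.05)
  expect_true(all(v2 == -4))               # sd = 0 degenerates to the mean
  # one synthetic animal shares its replicate_id across the cell's variables
  expect_length(unique(big$observations$replicate_id), 10000)
  expect_true(all(table(big$observations$replicate_id) == 2))
  again <- simulate_replicates_from_summary(tab, n_sim = 10, seed = 5)
  twice <- simulate_replicates_from_summary(tab, n_sim = 10, seed = 5)
  expect_identical(again$observations, twice$observations)
  expect_error(simulate_replicates_from_summary(
    transform(tab, sd = c(-1, 0)), 5, 1), "negative sd")
})

test_that("subset_design drops dependent time points as the paired design requires", {
  pm <- study_fixture("aorta", replicate_noise_sd = 0, measurement_noise_sd = 0,
                      n_reps_Y = 2, paired = TRUE)
  ds <- generate_planted(pm)$dataset
  expect_length(ds$design$times$Y, 6)
  sub <- subset_design(ds, keep_Y_times = c(0, 4, 14, 28))
  expect_equal(sub$design$times$Y, c(0, 4, 14, 28))
  expect_length(sub$design$times$X, 4)     # X grid untouched
  # identity and precondition
  expect_equal(subset_design(ds)$observations, ds$observations)
  expect_error(subset_design(ds, keep_X_times = c(0, 99)), "absent from the design")
})

test_that("CSV round trip preserves the dataset and nesting is whole-replicate", {
  ds <- toy_dataset(n_reps = 2, seed = 3, paired = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_long_csv(ds, path)
  back <- read_long_csv(path)
  cols <- c("condition", "time", "variable", "block", "replicate_id",
            "pairing_id", "value")
  o1 <- ds$observations[cols]; o2 <- back$observations[cols]
  o1 <- o1[do.call(order, o1), ]; o2 <- o2[do.call(order, o2), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2, ignore_attr = TRUE)

  # removing a replicate_id removes every observation it contributed
  obs <- ds$observations
  keep <- !(obs$block == "X" & obs$condition == "a" & obs$time == 0 &
              obs$replicate_id == "r1")
  red <- nested_dataset(obs[keep, ])
  expect_equal(nrow(obs) - nrow(red$observations),
               length(ds$design$variables$X))
})
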