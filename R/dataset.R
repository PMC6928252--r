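#' Replicated, nested, fully crossed condition x time datasets
#'
#' A `nested_dataset` holds long-format observations from a fully crossed
#' condition x time study in which measurements are nested within biological
#' replicates (animals): one `replicate_id` groups every variable that animal
#' contributed to one condition x time cell, so resampling a replicate moves
#' all of its observations together. The independent block (`X`, e.g.
#' histology) and the dependent block (`Y`, e.g. mechanics) may use different
#' time grids and variable sets, but share the condition axis. An optional
#' `pairing_id` links the X and Y observations that came from the same animal.
#'
#' @param observations data.frame with columns `condition`, `time` (numeric),
#'   `variable`, `block` (`"X"` or `"Y"`), `replicate_id`, `value`, and
#'   optionally `pairing_id` and `time_unit`.
#' @param time_unit unit for the time axis (e.g. `"day"`, `"hour"`); used only
#'   for reporting.
#' @return An object of class `nested_dataset`: a list with `observations`
#'   (validated long table), `design` (conditions; per-block time grids and
#'   variable lists) and `replicate_counts` (replicates per block x condition
#'   x time cell).
#' @examples
#' obs <- expand.grid(condition = "c1", time = 0, variable = c("v1", "v2"),
#'                    block = "X", replicate_id = c("a1", "a2"),
#'                    stringsAsFactors = FALSE)
#' obs$value <- seq_len(nrow(obs))
#' obs_y <- obs; obs_y$block <- "Y"; obs_y$variable <- sub("v", "o", obs_y$variable)
#' ds <- nested_dataset(rbind(obs, obs_y))
#' ds$replicate_counts
#' @export
nested_dataset <- function(observations, time_unit = "day") {
  required <- c("condition", "time", "variable", "block", "replicate_id", "value")
  missing_cols <- setdiff(required, names(observations))
  if (length(missing_cols) > 0)
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  obs <- as.data.frame(observations, stringsAsFactors = FALSE)
  if (!"pairing_id" %in% names(obs)) obs$pairing_id <- NA_character_
  if ("time_unit" %in% names(obs)) {
    units <- unique(obs$time_unit)
    if (length(units) > 1) stopf("mixed time units: %s", paste(units, collapse = ", "))
    time_unit <- units
  }
  obs$condition <- as.character(obs$condition)
  obs$variable <- as.character(obs$variable)
  obs$block <- as.character(obs$block)
  obs$replicate_id <- as.character(obs$replicate_id)
  obs$pairing_id <- as.character(obs$pairing_id)
  obs$time <- as.numeric(obs$time)
  obs$value <- as.numeric(obs$value)
  if (any(!is.finite(obs$time))) stopf("non-finite time values")
  if (any(!is.finite(obs$value))) stopf("non-finite measurement values")
  if (!all(obs$block %in% c("X", "Y")))
    stopf("block must be 'X' or 'Y'; found: %s",
          paste(setdiff(unique(obs$block), c("X", "Y")), collapse = ", "))

  design <- list(
    conditions = sort(unique(obs$condition)),
    times = lapply(split(obs$time, obs$block), function(t) sort(unique(t))),
    variables = lapply(split(obs$variable, obs$block), function(v) sort(unique(v))),
    time_unit = time_unit
  )
  ds <- structure(list(observations = obs, design = design), class = "nested_dataset")
  validate_nested_dataset(ds)
}

#' @noRd
validate_nested_dataset <- function(ds) {
  obs <- ds$observations
  d <- ds$design

  if (all(c("X", "Y") %in% obs$block)) {
    cx <- unique(obs$condition[obs$block == "X"])
    cy <- unique(obs$condition[obs$block == "Y"])
    if (!setequal(cx, cy))
      stopf("condition labels differ between blocks (mode 1 is shared): X has {%s}, Y has {%s}",
            paste(sort(cx), collapse = ","), paste(sort(cy), collapse = ","))
  }

  key <- paste(obs$block, obs$condition, obs$time, obs$variable, obs$replicate_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- obs[duplicated(key), c("block", "condition", "time", "variable", "replicate_id")]
    stopf("duplicate observation rows for (cell, replicate, variable): %s",
          paste(utils::capture.output(print(utils::head(dup, 3))), collapse = "; "))
  }

  # dense design: every condition x time x variable cell of a block must exist
  for (b in unique(obs$block)) {
    o <- obs[obs$block == b, ]
    grid <- expand.grid(condition = d$conditions, time = d$times[[b]],
                        variable = d$variables[[b]], stringsAsFactors = FALSE)
    have <- unique(paste(o$condition, o$time, o$variable, sep = "\r"))
    want <- paste(grid$condition, grid$time, grid$variable, sep = "\r")
    absent <- grid[!(want %in% have), , drop = FALSE]
    if (nrow(absent) > 0)
      stopf("block %s: designed cell(s) with zero replicates, e.g. condition=%s time=%s variable=%s",
            b, absent$condition[1], absent$time[1], absent$variable[1])
    # nesting: within a cell every replicate must cover every variable
    cell <- paste(o$condition, o$time, sep = "\r")
    for (cl in unique(cell)) {
      oc <- o[cell == cl, ]
      tab <- table(oc$replicate_id)
      if (length(unique(tab)) > 1 || unique(tab)[1] != length(d$variables[[b]]))
        stopf("block %s cell (%s): replicates do not each cover all %d variables",
              b, gsub("\r", ", ", cl), length(d$variables[[b]]))
      # pairing consistency: one pairing_id <-> one replicate_id within the cell
      pp <- unique(oc[!is.na(oc$pairing_id), c("replicate_id", "pairing_id")])
      if (nrow(pp) > 0 &&
          (anyDuplicated(pp$pairing_id) || anyDuplicated(pp$replicate_id)))
        stopf("block %s cell (%s): pairing_id collision (one animal mapped to two replicates or vice versa)",
              b, gsub("\r", ", ", cl))
    }
  }

  counts <- unique(obs[, c("block", "condition", "time", "replicate_id")])
  rc <- stats::aggregate(list(n_replicates = counts$replicate_id),
                         by = counts[, c("block", "condition", "time")],
                         FUN = length)
  rc <- rc[order(rc$block, rc$condition, rc$time), ]
  rownames(rc) <- NULL
  ds$replicate_counts <- rc
  ds
}

#' @export
print.nested_dataset <- function(x, ...) {
  d <- x$design
  cat("<nested_dataset>\n")
  cat(sprintf("  conditions: %s\n", paste(d$conditions, collapse = ", ")))
  for (b in names(d$times))
    cat(sprintf("  block %s: %d variables x %d times (%s %s)\n", b,
                length(d$variables[[b]]), length(d$times[[b]]),
                paste(d$times[[b]], collapse = ","), d$time_unit))
  cat(sprintf("  %d observations, replicates per cell %s\n",
              nrow(x$observations),
              paste(range(x$replicate_counts$n_replicates), collapse = "-")))
  invisible(x)
}

#' Read a long-format CSV into a nested dataset
#'
#' Canonical columns are `condition, time, time_unit, variable, block,
#' replicate_id, pairing_id, value`; `schema` maps nonstandard file column
#' names onto them, e.g. `list(condition = "region", value = "measurement")`.
#'
#' @param path CSV file path.
#' @param schema optional named list mapping canonical names to file column
#'   names.
#' @return A [nested_dataset()].
#' @examples
#' ds <- read_long_csv(system.file("extdata", "example_long.csv",
#'                                 package = "nplsnest"))
#' ds
#' @export
read_long_csv <- function(path, schema = NULL) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(raw)) stopf("schema column '%s' not in file", src)
      names(raw)[names(raw) == src] <- canonical
    }
  }
  nested_dataset(raw)
}

#' Write a nested dataset to long-format CSV
#'
#' Inverse of [read_long_csv()]; round-trips exactly (values are written with
#' full precision).
#' @param dataset a [nested_dataset()].
#' @param path output file path.
#' @export
write_long_csv <- function(dataset, path) {
  obs <- dataset$observations
  obs$time_unit <- dataset$design$time_unit
  obs <- obs[, c("condition", "time", "time_unit", "variable", "block",
                 "replicate_id", "pairing_id", "value")]
  utils::write.csv(obs, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Average replicates into a dense tensor pair
#'
#' Builds the global-average arrays: `X` of shape conditions x X-times x
#' X-variables and `Y` of shape conditions x Y-times x Y-variables, each entry
#' the arithmetic mean over that cell's replicates.
#'
#' @param dataset a [nested_dataset()].
#' @return A `tensor_pair`: list with dense arrays `X` and `Y` carrying
#'   dimnames (conditions, times, variables).
#' @export
average_replicates <- function(dataset) {
  d <- dataset$design
  obs <- dataset$observations
  build <- function(b) {
    o <- obs[obs$block == b, ]
    if (nrow(o) == 0) return(NULL)
    i <- length(d$conditions); j <- length(d$times[[b]]); k <- length(d$variables[[b]])
    means <- stats::aggregate(list(value = o$value),
                              by = o[, c("condition", "time", "variable")],
                              FUN = mean)
    arr <- array(NA_real_, dim = c(i, j, k),
                 dimnames = list(d$conditions, as.character(d$times[[b]]),
                                 d$variables[[b]]))
    idx <- cbind(match(means$condition, d$conditions),
                 match(means$time, d$times[[b]]),
                 match(means$variable, d$variables[[b]]))
    arr[idx] <- means$value
    if (anyNA(arr)) {
      miss <- which(is.na(arr), arr.ind = TRUE)[1, ]
      stopf("block %s: designed cell with zero replicates at condition=%s time=%s variable=%s",
            b, d$conditions[miss[1]], d$times[[b]][miss[2]], d$variables[[b]][miss[3]])
    }
    arr
  }
  tensor_pair(build("X"), build("Y"))
}

#' Construct a tensor pair
#'
#' @param X numeric array, conditions x times x variables (independent block).
#' @param Y numeric array, conditions x times x variables (dependent block);
#'   first dimension must match `X`.
#' @return object of class `tensor_pair`.
#' @export
tensor_pair <- function(X, Y) {
  for (nm in c("X", "Y")) {
    a <- get(nm)
    if (is.null(a)) next
    if (length(dim(a)) != 3) stopf("%s must be a 3-way array", nm)
    if (anyNA(a)) stopf("%s contains missing entries; tensors must be dense", nm)
  }
  if (!is.null(X) && !is.null(Y) && dim(X)[1] != dim(Y)[1])
    stopf("X and Y must share the first (condition) dimension: %d vs %d",
          dim(X)[1], dim(Y)[1])
  structure(list(X = X, Y = Y), class = "tensor_pair")
}

#' @export
print.tensor_pair <- function(x, ...) {
  cat(sprintf("<tensor_pair> X: %s | Y: %s\n",
              paste(dim(x$X), collapse = "x"), paste(dim(x$Y), collapse = "x")))
  invisible(x)
}

#' Simulate nested replicates from summary statistics
#'
#' For studies publishing only per-cell means and standard deviations, draws
#' `n_sim` independent normal replicates per condition x time x variable cell.
#' Draws for one synthetic animal share a `replicate_id` across all variables
#' of its cell, so the simulated data carry the same nesting structure as raw
#' replicates (the animal-level draw itself is independent per variable, as a
#' summary table carries no covariance information).
#'
#' @param table data.frame with columns `block`, `condition`, `time`,
#'   `variable`, `mean`, `sd` (and optionally `n`, ignored in favour of
#'   `n_sim`).
#' @param n_sim replicates to draw per cell (>= 1).
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @param time_unit unit label for the time axis.
#' @return a [nested_dataset()].
#' @export
simulate_replicates_from_summary <- function(table, n_sim, seed, time_unit = "hour") {
  required <- c("block", "condition", "time", "variable", "mean", "sd")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0)
    stopf("summary table missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (n_sim < 1) stopf("n_sim must be >= 1")
  if (any(table$sd < 0)) stopf("negative sd in summary table")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(table)), function(r) {
      tr <- table[r, ]
      data.frame(condition = tr$condition, time = tr$time, variable = tr$variable,
                 block = tr$block,
                 replicate_id = sprintf("sim%02d", seq_len(n_sim)),
                 pairing_id = NA_character_,
                 value = stats::rnorm(n_sim, tr$mean, tr$sd),
                 stringsAsFactors = FALSE)
    })
    nested_dataset(do.call(rbind, rows), time_unit = time_unit)
  })
}

#' Restrict a dataset to a subset of the time grids
#'
#' Used e.g. when paired X/Y resampling requires dropping dependent-block time
#' points that have no paired independent observations.
#'
#' @param dataset a [nested_dataset()].
#' @param keep_X_times,keep_Y_times numeric time values to keep in each block;
#'   `NULL` keeps the full grid.
#' @return the restricted, re-validated [nested_dataset()].
#' @export
subset_design <- function(dataset, keep_X_times = NULL, keep_Y_times = NULL) {
  obs <- dataset$observations
  for (b in c("X", "Y")) {
    keep <- if (b == "X") keep_X_times else keep_Y_times
    if (is.null(keep)) next
    grid <- dataset$design$times[[b]]
    bad <- setdiff(keep, grid)
    if (length(bad) > 0)
      stopf("block %s: requested time(s) absent from the design: %s",
            b, paste(bad, collapse = ", "))
    if (length(keep) == 0) stopf("block %s: empty resulting time grid", b)
    obs <- obs[!(obs$block == b & !(obs$time %in% keep)), ]
  }
  nested_dataset(obs, time_unit = dataset$design$time_unit)
}
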