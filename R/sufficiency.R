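# Reference-size sufficiency simulation: how often does a fresh array fall
# outside the per-probeset min-max range of a hypothetical common reference
# of a given size? For iid continuous data the expected rate is the
# order-statistics coverage law 2/(s+1).

.row_min <- function(m) do.call(pmin, c(as.data.frame(m), list(na.rm = FALSE)))
.row_max <- function(m) do.call(pmax, c(as.data.frame(m), list(na.rm = FALSE)))

#' False-estimation rate of per-probeset dynamic range
#'
#' Draws `ref_size` pool columns without replacement as a hypothetical
#' common reference plus one distinct "actual sample" column, and reports
#' the percentage of probesets whose actual-sample value falls outside the
#' untrimmed min-max range of the drawn reference. Only the ordering of
#' values matters, so the rate is invariant to any monotone transform of
#' the pool.
#'
#' @param pool Numeric matrix, probesets x samples (at least
#'   `ref_size + 1` columns).
#' @param ref_size Number of reference columns to draw.
#' @param seed Optional seed for the draw.
#' @param ref_cols,actual_col Optional explicit column choices (bypass the
#'   random draw); `actual_col` must not be among `ref_cols`.
#' @return Percentage in `[0, 100]`.
#' @export
false_estimation_rate <- function(pool, ref_size, seed = NULL,
                                  ref_cols = NULL, actual_col = NULL) {
  if (!is.matrix(pool)) stop("pool must be a matrix")
  if (is.null(ref_cols)) {
    if (ref_size >= ncol(pool))
      stop("ref_size (", ref_size, ") must be smaller than the pool (",
           ncol(pool), " columns)")
    if (!is.null(seed)) set.seed(seed)
    draw <- sample.int(ncol(pool), ref_size + 1L)
    ref_cols <- draw[seq_len(ref_size)]
    actual_col <- draw[ref_size + 1L]
  } else {
    if (is.null(actual_col)) stop("actual_col required with explicit ref_cols")
    if (actual_col %in% ref_cols)
      stop("the actual sample must be distinct from the reference draw")
  }
  sub <- pool[, ref_cols, drop = FALSE]
  lo <- .row_min(sub)
  hi <- .row_max(sub)
  a <- pool[, actual_col]
  100 * mean(a < lo | a > hi)
}

#' Reference-size grid experiment
#'
#' Repeats [false_estimation_rate()] over a grid of hypothetical reference
#' sizes, with `n_replicates` independent draws per size, and repeats the
#' whole experiment `n_experiments` times; reports per-experiment per-size
#' mean and standard error plus grand averages. With an iid continuous pool
#' the mean rate at size s is 100*2/(s+1) percent, decreasing roughly
#' exponentially along a doubling size grid.
#'
#' @param pool Numeric matrix, probesets x samples; needs at least
#'   `max(sizes) + 1` columns.
#' @param sizes Reference sizes to test (default doubling grid 10..5120).
#' @param n_replicates Draws per size within one experiment (default 10).
#' @param n_experiments Independent repeats of the whole grid (default 5).
#' @param seed Master seed; experiment streams are derived from it by fixed
#'   offsets, so the report is fully reproducible.
#' @return A `"sufficiency_report"`: list with `sizes`, `rates`
#'   (experiments x sizes x replicates array), per-experiment `mean` and
#'   `sem` matrices, `grand_mean`/`grand_sem` per size, and the seed.
#' @examples
#' pool <- generate_reference_pool(80, 50, mix = c(noisy_unimodal = 1),
#'                                 seed = 7)$matrix
#' rep <- size_grid_experiment(pool, sizes = c(10, 20, 40), seed = 7)
#' rep
#' @export
size_grid_experiment <- function(pool,
                                 sizes = c(10, 20, 40, 80, 160, 320, 640,
                                           1280, 2560, 5120),
                                 n_replicates = 10, n_experiments = 5,
                                 seed = 1) {
  sizes <- as.integer(sizes)
  if (any(sizes < 1L)) stop("sizes must be positive")
  if (max(sizes) >= ncol(pool))
    stop("pool too small: largest size ", max(sizes),
         " needs at least ", max(sizes) + 1L, " columns")
  rates <- array(NA_real_,
                 dim = c(n_experiments, length(sizes), n_replicates),
                 dimnames = list(paste0("exp", seq_len(n_experiments)),
                                 as.character(sizes), NULL))
  for (e in seq_len(n_experiments)) {
    set.seed((seed + 7919L * e) %% 2147483629L)  # fixed per-experiment offset
    for (si in seq_along(sizes)) {
      for (r in seq_len(n_replicates)) {
        rates[e, si, r] <- false_estimation_rate(pool, sizes[si])
      }
    }
  }
  mean_es <- apply(rates, c(1, 2), mean)
  sem_es <- apply(rates, c(1, 2), stats::sd) / sqrt(n_replicates)
  all_by_size <- apply(rates, 2, c)
  structure(
    list(sizes = sizes,
         rates = rates,
         mean = mean_es,
         sem = sem_es,
         grand_mean = colMeans(all_by_size),
         grand_sem = apply(all_by_size, 2, stats::sd) /
           sqrt(n_replicates * n_experiments),
         n_replicates = n_replicates,
         n_experiments = n_experiments,
         n_probesets = nrow(pool),
         seed = seed),
    class = "sufficiency_report"
  )
}

#' @export
print.sufficiency_report <- function(x, digits = 3, ...) {
  cat("Reference-size sufficiency report (",
      x$n_experiments, " experiments x ", x$n_replicates,
      " replicates, ", x$n_probesets, " probesets, seed ", x$seed, ")\n",
      sep = "")
  tab <- rbind(x$mean, average = x$grand_mean)
  print(round(tab, digits))
  invisible(x)
}

#' @export
as.data.frame.sufficiency_report <- function(x, ...) {
  grid <- expand.grid(experiment = seq_len(x$n_experiments),
                      size = x$sizes,
                      replicate = seq_len(x$n_replicates))
  grid$rate <- mapply(function(e, s, r) x$rates[e, which(x$sizes == s), r],
                      grid$experiment, grid$size, grid$replicate)
  grid
}

#' Write a sufficiency report as CSV
#'
#' Rows are experiments plus a grand-average row; columns are reference
#' sizes; cells hold "mean±sem" percentages.
#'
#' @param report A `"sufficiency_report"`.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_sufficiency_csv <- function(report, path) {
  stopifnot(inherits(report, "sufficiency_report"))
  fmt <- function(m, s) sprintf("%.3f±%.3f", m, s)
  rows <- lapply(seq_len(report$n_experiments), function(e)
    fmt(report$mean[e, ], report$sem[e, ]))
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, fmt(report$grand_mean, report$grand_sem))
  df <- data.frame(Exp = c(as.character(seq_len(report$n_experiments)),
                           "Average"),
                   tab, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("Exp", as.character(report$sizes))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a sufficiency report as JSON
#'
#' @param report A `"sufficiency_report"`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_sufficiency_json <- function(report, path) {
  stopifnot(inherits(report, "sufficiency_report"))
  obj <- list(sizes = report$sizes,
              mean = unname(apply(report$mean, 2, as.numeric)),
              sem = unname(apply(report$sem, 2, as.numeric)),
              grand_mean = unname(report$grand_mean),
              grand_sem = unname(report$grand_sem),
              n_replicates = report$n_replicates,
              n_experiments = report$n_experiments,
              n_probesets = report$n_probesets,
              seed = report$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
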