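# Independent brute-force oracles and small fixture builders shared across
# the test files. These deliberately avoid the package's own code paths.

# exhaustive split-search oracle for the step fit: scans every admissible k
# and scores it with plain two-pass means and sums of squares
brute_step <- function(v, min_side_fraction = 0.05) {
  n <- length(v)
  k_min <- max(1L, as.integer(ceiling(min_side_fraction * n)))
  best <- NULL
  for (k in k_min:(n - k_min)) {
    lo <- v[1:k]
    hi <- v[(k + 1):n]
    sse <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(k = k, sse = sse, low_mean = mean(lo), high_mean = mean(hi))
    }
  }
  best
}

# rank-counting oracle for the signed percentile of `value` among the
# reference values `row` with threshold `thr`
rank_percentile_oracle <- function(row, thr, value) {
  if (value == thr) return(0)
  if (value > thr) {
    m <- sum(row >= thr)
    if (m == 0) return(100)
    min(100, 100 * sum(row >= thr & row <= value) / m)
  } else {
    p <- sum(row < thr)
    if (p == 0) return(-100)
    max(-100, -100 * sum(row < thr & row >= value) / p)
  }
}

# quantile oracle: manual linear interpolation between order statistics
# (the "type 7" rule, written out independently)
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# reference built without the small-pool warning
quiet_reference <- function(pool, ...) {
  suppressWarnings(build_common_reference(pool, ...))
}

# A small controlled model: a reference of clean two-level probesets plus
# three populations whose intensities are placed to force known calls.
make_toy_model <- function() {
  pool <- toy_step_pool(n_probesets = 4)
  ref <- quiet_reference(pool, normalize = FALSE, min_side_fraction = 0.1)
  lo <- vapply(ref$profiles, `[[`, numeric(1), "min")
  hi <- vapply(ref$profiles, `[[`, numeric(1), "max")
  want <- rbind(popA = c("HIGH", "HIGH", "LOW", "LOW"),
                popB = c("HIGH", "LOW", "LOW", "HIGH"),
                popC = c("HIGH", "LOW", "HIGH", "LOW"))
  colnames(want) <- ref$probeset_ids
  profiles <- lapply(rownames(want), function(p) {
    x <- ifelse(want[p, ] == "HIGH", hi, lo)
    names(x) <- ref$probeset_ids
    build_population_profile(x, ref, name = p)
  })
  list(model = expression_model("toy", profiles, ref),
       ref = ref, want = want)
}

# a tiny reference whose calls are fully controlled: each probeset row is a
# clean two-level step, so thresholds sit midway between the levels
toy_step_pool <- function(n_probesets = 4, n_samples = 12,
                          low = 2, high = 8) {
  m <- matrix(rep(c(rep(low, n_samples / 2), rep(high, n_samples / 2)),
                  each = n_probesets),
              nrow = n_probesets)
  # stagger levels so trimmed dynamic ranges differ across probesets
  m <- m + (seq_len(n_probesets) - 1) * 0.001
  m <- m * matrix(rep(seq(1, 1 + 0.1 * (n_probesets - 1), by = 0.1),
                      n_samples), n_probesets)
  rownames(m) <- sprintf("tp_%02d", seq_len(n_probesets))
  colnames(m) <- sprintf("c_%02d", seq_len(n_samples))
  m
}
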