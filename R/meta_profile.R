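# Per-probeset meta-profile: reference distribution, threshold, trimmed
# dynamic range, signed-percentile mapping and high/low classification.

#' Build a probeset meta-profile from reference values
#'
#' Summarizes one probeset's reference distribution into the quantities used
#' for absolute expression calls: the step-fit high/low threshold, the
#' minimum and maximum, the trimmed quantile bounds used for dynamic-range
#' reporting, and the sorted low-side / high-side values that anchor the
#' signed-percentile scale.
#'
#' The trim (default 0.5% at each end) affects only the reported trimmed
#' bounds; threshold fitting always sees the full vector.
#'
#' @param values Numeric vector of log2 intensities (sorted internally).
#' @param probeset_id Identifier for the probeset.
#' @param trim_fraction Fraction trimmed at each tail for the trimmed
#'   dynamic-range bounds, in `[0, 0.5)`. Default 0.005.
#' @param min_side_fraction,alpha Passed to [fit_step_threshold()].
#'
#' @return An object of class `"meta_profile"`: a list with `probeset_id`,
#'   `n`, `threshold`, `min`, `max`, `trimmed_low`, `trimmed_high`,
#'   `low_side` (sorted values below the threshold), `high_side` (sorted
#'   values at or above it) and the underlying `step_fit`.
#'
#' @examples
#' mp <- build_meta_profile(c(1, 1, 1, 5, 5, 5), "toy")
#' mp$threshold
#' dynamic_range(mp)
#' @export
build_meta_profile <- function(values, probeset_id = "probeset",
                               trim_fraction = 0.005,
                               min_side_fraction = 0.05, alpha = 0.05) {
  if (!(trim_fraction >= 0 && trim_fraction < 0.5))
    stop("trim_fraction must lie in [0, 0.5)")
  values <- unname(sort(values))
  fit <- fit_step_threshold(values, min_side_fraction = min_side_fraction,
                            alpha = alpha, probeset_id = probeset_id)
  thr <- fit$threshold
  # linear interpolation between order statistics (type 7)
  q <- stats::quantile(values, c(trim_fraction, 1 - trim_fraction),
                       type = 7, names = FALSE)
  low_side <- values[values < thr]
  high_side <- values[values >= thr]
  structure(
    list(
      probeset_id = probeset_id,
      n = length(values),
      threshold = thr,
      min = values[1L],
      max = values[length(values)],
      trimmed_low = q[1L],
      trimmed_high = q[2L],
      low_side = low_side,
      high_side = high_side,
      step_fit = fit
    ),
    class = "meta_profile"
  )
}

#' Dynamic range of a meta-profile
#'
#' The spread of a probeset's reference values: `max - min` (untrimmed) or
#' `trimmed_high - trimmed_low` (the highest and lowest 0.5% of points
#' ignored, with the default trim). The trimmed range is the one used to
#' rank probesets by informativeness.
#'
#' @param profile A `"meta_profile"`.
#' @param trimmed Use the trimmed quantile bounds? Default `FALSE`.
#' @return Non-negative log2-scale spread.
#' @export
dynamic_range <- function(profile, trimmed = FALSE) {
  stopifnot(inherits(profile, "meta_profile"))
  if (trimmed) profile$trimmed_high - profile$trimmed_low
  else profile$max - profile$min
}

# Percentile anchors for one side. For the high side the anchor at each
# distinct value x is 100 * #(high_side <= x) / |high_side|; the low side is
# the mirror, -100 * #(low_side >= x) / |low_side|, so the reference minimum
# maps to -100 and the maximum to +100 exactly.
.side_anchors <- function(profile) {
  thr <- profile$threshold
  hi <- profile$high_side
  lo <- profile$low_side
  hx <- unique(hi[hi > thr])
  hy <- if (length(hx)) 100 * findInterval(hx, hi) / length(hi) else numeric(0)
  lx <- unique(lo)
  ly <- numeric(0)
  if (length(lx)) {
    # #(lo >= x) = n_lo - #(lo <= x) + multiplicity(x), for x a member of lo
    n_lo <- length(lo)
    geq <- n_lo - findInterval(lx, lo) + tabulate(match(lo, lx), length(lx))
    ly <- -100 * geq / n_lo
  }
  list(high_x = hx, high_y = hy, low_x = lx, low_y = ly)
}

#' Signed expression percentile of a value within a meta-profile
#'
#' Positions a (normalized) expression value on the probeset's reference
#' scale: the threshold maps to 0, the reference maximum to +100, the
#' reference minimum to -100, and values in between are placed by rank
#' interpolation within the high or low side. Values beyond the observed
#' range clamp to +/-100. The mapping is monotone non-decreasing in the
#' value.
#'
#' @param profile A `"meta_profile"`.
#' @param value Numeric vector of log2 intensities to map.
#' @param method `"rank"` (default): rank interpolation within each side;
#'   `"linear"`: linear in intensity between the threshold and the side's
#'   extreme.
#' @return Numeric vector in `[-100, 100]`.
#' @export
percentile_of <- function(profile, value, method = c("rank", "linear")) {
  stopifnot(inherits(profile, "meta_profile"))
  method <- match.arg(method)
  thr <- profile$threshold
  out <- numeric(length(value))
  hi <- which(value > thr)
  lo <- which(value < thr)
  # value == threshold -> 0 already

  if (method == "linear") {
    if (length(hi)) {
      den <- profile$max - thr
      out[hi] <- if (den > 0) pmin(100, 100 * (value[hi] - thr) / den) else 100
    }
    if (length(lo)) {
      den <- thr - profile$min
      out[lo] <- if (den > 0) pmax(-100, -100 * (thr - value[lo]) / den) else -100
    }
    return(out)
  }

  a <- .side_anchors(profile)
  if (length(hi)) {
    if (length(a$high_x) == 0L) {
      out[hi] <- 100                       # above an empty/degenerate high side
    } else {
      out[hi] <- stats::approx(c(thr, a$high_x), c(0, a$high_y),
                               xout = value[hi], rule = 2)$y
    }
  }
  if (length(lo)) {
    if (length(a$low_x) == 0L) {
      out[lo] <- -100                      # below an empty low side
    } else {
      out[lo] <- stats::approx(c(a$low_x, thr), c(a$low_y, 0),
                               xout = value[lo], rule = 2)$y
    }
  }
  out
}

#' Classify a value as low/high with a four-band grade
#'
#' The binary call is `HIGH` when the value is at or above the probeset's
#' threshold and `LOW` otherwise. The band refines the call by percentile:
#' `VERY_HIGH` at or above `band_cut`, `VERY_LOW` at or below `-band_cut`,
#' `HIGH`/`LOW` in between on the matching side. The band cut is
#' configurable (default 50) because the four-band display convention does
#' not fix it numerically.
#'
#' @param profile A `"meta_profile"`.
#' @param value Numeric vector of log2 intensities.
#' @param band_cut Absolute percentile separating the "very" bands, in
#'   (0, 100). Default 50.
#' @param method Percentile method, see [percentile_of()].
#' @return A data.frame with columns `value`, `percentile`, `call`
#'   (`LOW`/`HIGH`) and `band` (`VERY_LOW`/`LOW`/`HIGH`/`VERY_HIGH`).
#' @export
classify <- function(profile, value, band_cut = 50,
                     method = c("rank", "linear")) {
  stopifnot(inherits(profile, "meta_profile"))
  if (!(band_cut > 0 && band_cut < 100)) stop("band_cut must lie in (0, 100)")
  p <- percentile_of(profile, value, method = method)
  call <- ifelse(value >= profile$threshold, "HIGH", "LOW")
  band <- ifelse(p >= band_cut, "VERY_HIGH",
          ifelse(p >= 0, "HIGH",
          ifelse(p > -band_cut, "LOW", "VERY_LOW")))
  data.frame(value = value, percentile = p, call = call, band = band,
             stringsAsFactors = FALSE)
}

#' Histogram of a meta-profile's reference distribution
#'
#' Equal-width bins spanning `[min, max]`; counts always sum to the number
#' of reference values. Display support for the meta-profile graphic.
#'
#' @param profile A `"meta_profile"`.
#' @param n_bins Number of bins (>= 1). Default 30.
#' @return A list with `edges` (length `n_bins + 1`) and `counts`
#'   (length `n_bins`).
#' @export
profile_histogram <- function(profile, n_bins = 30L) {
  stopifnot(inherits(profile, "meta_profile"))
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  values <- c(profile$low_side, profile$high_side)
  if (profile$min == profile$max) {
    edges <- seq(profile$min - 0.5, profile$max + 0.5, length.out = n_bins + 1)
    counts <- integer(n_bins)
    counts[max(1L, ceiling(n_bins / 2))] <- profile$n
    return(list(edges = edges, counts = counts))
  }
  edges <- seq(profile$min, profile$max, length.out = n_bins + 1)
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  list(edges = edges, counts = tabulate(idx, nbins = n_bins))
}

#' @export
print.meta_profile <- function(x, ...) {
  cat("Meta-profile", x$probeset_id, "(n =", x$n, "reference values)\n")
  cat(sprintf("  range [%.3g, %.3g]   trimmed [%.3g, %.3g]\n",
              x$min, x$max, x$trimmed_low, x$trimmed_high))
  cat(sprintf("  high/low threshold %.3g   (%d low / %d high)\n",
              x$threshold, length(x$low_side), length(x$high_side)))
  invisible(x)
}
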