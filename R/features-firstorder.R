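#' First-order intensity statistics of an ROI
#'
#' The 19-feature first-order family: Energy, TotalEnergy, Entropy,
#' Minimum, 10Percentile, 90Percentile, Maximum, Mean, Median,
#' InterquartileRange, Range, MeanAbsoluteDeviation,
#' RobustMeanAbsoluteDeviation, RootMeanSquared, StandardDeviation,
#' Skewness, Kurtosis, Variance, Uniformity. Variance and standard
#' deviation are population statistics; kurtosis is not excess-corrected;
#' Entropy and Uniformity are computed on the discretized gray-level
#' histogram.
#'
#' @param volume numeric 3D array.
#' @param roi logical array marking ROI voxels (non-empty).
#' @param spacing_mm voxel spacing (for TotalEnergy).
#' @param n_bins gray levels for the entropy/uniformity histogram.
#' @return named numeric vector of length 19.
#' @export
first_order_features <- function(volume, roi, spacing_mm = c(0.5, 0.5, 0.5),
                                 n_bins = 32) {
  if (!any(roi)) stop("ROI is empty")
  x <- volume[roi]
  codes <- discretize_codes(x, n_bins)
  first_order_from_vals(x, codes, n_bins, spacing_mm)
}

# linear-interpolation (type 7) quantile on a pre-sorted vector
quantile7 <- function(xs, p) {
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- pmin(floor(h), n)
  hi <- pmin(lo + 1, n)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

first_order_from_vals <- function(x, codes, n_bins, spacing_mm) {
  n <- length(x)
  mo <- .cpp_moments(x)
  m <- mo[["mean"]]; m2 <- mo[["m2"]]; energy <- mo[["energy"]]
  p <- tabulate(codes, n_bins) / n
  p_nz <- p[p > 0]
  xs <- sort.int(x, method = "quick")
  q <- quantile7(xs, c(0.10, 0.25, 0.50, 0.75, 0.90))
  # robust block: values inside the 10th-90th percentile window
  lo_i <- findInterval(q[1], xs) # first index with xs >= q[1]
  lo_i <- if (lo_i > 0 && xs[lo_i] >= q[1]) lo_i else lo_i + 1
  hi_i <- findInterval(q[5], xs)
  robust <- xs[lo_i:hi_i]
  c(Energy = energy,
    TotalEnergy = prod(spacing_mm) * energy,
    Entropy = -sum(p_nz * log2(p_nz)),
    Minimum = mo[["min"]],
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = mo[["max"]],
    Mean = m,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = mo[["max"]] - mo[["min"]],
    MeanAbsoluteDeviation = mo[["mad"]],
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(energy / n),
    StandardDeviation = sqrt(m2),
    Skewness = if (m2 > 0) mo[["m3"]] / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mo[["m4"]] / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}
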