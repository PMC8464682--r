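#' ROI intensity histogram at full 16-bit depth
#'
#' Counts ROI voxels per exact gray level (identity binning over the
#' 0..65535 range — no gray-level reduction is applied anywhere in the
#' pipeline). The histogram is held sparsely: only occupied levels are
#' stored, with the nominal bin count (2^16) kept as metadata.
#'
#' @param volume 3D integer array (16-bit gray levels).
#' @param mask Logical 3D array of the same shape, non-empty.
#' @return Tibble with columns `value` (gray level) and `count`, sorted by
#'   value; attributes `total` (ROI voxel count) and `n_bins` (65536);
#'   class `intensity_histogram`.
#' @export
intensity_histogram <- function(volume, mask) {
  check_volume_mask(volume, mask)
  if (!any(mask)) stop("empty mask: no voxels to histogram")
  v <- as.integer(volume[mask])
  tab <- table(v)
  h <- tibble::tibble(value = as.integer(names(tab)), count = as.integer(tab))
  h <- h[order(h$value), ]
  attr(h, "total") <- length(v)
  attr(h, "n_bins") <- 65536L
  class(h) <- c("intensity_histogram", class(h))
  h
}

# The 12 histogram statistics shared by the first-order block and the
# LBP-TOP histograms. `values`/`counts` is a sparse histogram (occupied
# bins only); statistics are moments of the normalized bin probabilities
# p_b over the bin values b. Conventions the names don't pin down:
#   - sd/skewness/kurtosis are population moments; skewness and (excess)
#     kurtosis are defined as 0 when sd = 0;
#   - "max" is the highest bin probability; ties resolve to the smallest
#     bin value;
#   - "energy around" a peak sums p_b^2 over bins within `w` bin-value
#     units of it;
#   - relative maxima are plateaus of the nonempty-bin sequence strictly
#     above both nearest nonempty neighbours (a missing neighbour counts
#     as lower; a flat plateau counts once).
histogram_stats <- function(values, counts, w = 5) {
  stopifnot(length(values) == length(counts), length(values) > 0, all(counts >= 0))
  total <- sum(counts)
  if (total <= 0) stop("histogram has zero total count")
  keep <- counts > 0
  b <- as.numeric(values[keep])
  p <- counts[keep] / total

  mu <- sum(b * p)
  va <- sum((b - mu)^2 * p)
  sd <- sqrt(va)
  if (sd > 0) {
    sk <- sum(((b - mu) / sd)^3 * p)
    ku <- sum(((b - mu) / sd)^4 * p) - 3
  } else {
    sk <- 0
    ku <- 0
  }
  energy <- sum(p^2)
  entropy <- -sum(p * log2(p))
  pmax <- max(p)
  pos <- b[which.max(p)]  # b sorted ascending, which.max takes the first tie
  max_energy <- sum(p[abs(b - pos) <= w]^2)
  rng <- max(b) - min(b)

  # plateau run-length encoding of the nonempty-bin probability sequence
  r <- rle(p)
  np <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  left <- c(-Inf, r$values[-np])
  right <- c(r$values[-1], -Inf)
  is_peak <- r$values > left & r$values > right
  n_rel_max <- sum(is_peak)
  in_win <- rep(FALSE, length(b))
  for (k in which(is_peak)) {
    lo <- b[starts[k]] - w
    hi <- b[ends[k]] + w
    in_win <- in_win | (b >= lo & b <= hi)
  }
  rel_max_energy <- sum(p[in_win]^2)

  c(mean = mu, sd = sd, skewness = sk, kurtosis = ku,
    energy = energy, entropy = entropy,
    max = pmax, max_position = pos, max_energy = max_energy,
    range = rng, n_rel_max = as.numeric(n_rel_max),
    rel_max_energy = rel_max_energy)
}

#' First-order features of an ROI intensity histogram
#'
#' The 12 histogram statistics: mean, standard deviation, skewness, excess
#' kurtosis, energy, entropy (bits), maximum bin probability and its
#' position, energy in a window of half-width `w` gray levels around that
#' maximum, occupied range, number of relative maxima, and energy around
#' the relative maxima. Under identity binning the first four equal the
#' voxel-level moments.
#'
#' @param hist An [intensity_histogram()].
#' @param w Half-width, in gray levels, of the peak energy windows.
#' @return Named numeric vector of length 12 with names `fo_*`.
#' @export
first_order_features <- function(hist, w = 5) {
  stopifnot(inherits(hist, "intensity_histogram"))
  s <- histogram_stats(hist$value, hist$count, w = w)
  stats::setNames(s, paste0("fo_", names(s)))
}
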