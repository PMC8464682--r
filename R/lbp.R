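#' @name lbp
#' @title Local binary patterns over three orthogonal planes (LBP-TOP)
#'
#' @description
#' Classic radius-1, 8-neighbour local binary patterns computed in each of
#' the three orthogonal planes of the volume (XY, XZ, YZ) — the LBP-TOP
#' texture descriptor. For a voxel, the 8-bit code sets bit k when in-plane
#' neighbour k is at least as bright as the centre (ties set the bit), with
#' the ring starting at the +first-in-plane-axis neighbour and proceeding
#' counter-clockwise through the 3x3 ring; no sub-voxel interpolation.
#'
#' Four code variants are produced: `basic` (all 256 codes), `ri`
#' (rotation-invariant: the minimal value over circular bit rotations,
#' 36 codes), `u2` (the 58 uniform patterns — at most two 0/1 transitions
#' around the ring — each kept, all others pooled: 59 bins) and `riu2`
#' (uniform patterns mapped to their number of set bits 0..8, others pooled
#' to 9: 10 bins).
#'
#' Codes are computed for ROI voxels whose full in-plane 3x3 neighbourhood
#' lies inside the image grid (not necessarily inside the ROI: the
#' hull-expanded ROI deliberately includes rim tissue, so borrowing
#' adjacent gray values is consistent); other ROI voxels are skipped.
NULL

# ring offsets (first-axis, second-axis), counter-clockwise from (+1, 0)
lbp_ring <- cbind(o1 = c(1, 1, 0, -1, -1, -1, 0, 1),
                  o2 = c(0, 1, 1, 1, 0, -1, -1, -1))

# in-plane axis pairs in (z,y,x) component form; first axis then second
lbp_plane_axes <- function(plane) {
  switch(plane,
    XY = list(first = c(0, 0, 1), second = c(0, 1, 0)),  # x then y
    XZ = list(first = c(0, 0, 1), second = c(1, 0, 0)),  # x then z
    YZ = list(first = c(0, 1, 0), second = c(1, 0, 0)),  # y then z
    stop("plane must be one of XY, XZ, YZ"))
}

min_rotation <- function(code) {
  best <- code
  c <- code
  for (k in 1:7) {
    c <- bitwOr(bitwShiftR(c, 1), bitwShiftL(bitwAnd(c, 1L), 7L))
    if (c < best) best <- c
  }
  best
}

n_transitions <- function(code) {
  bits <- bitwAnd(bitwShiftR(code, 0:7), 1L)
  sum(bits != bits[c(2:8, 1)])
}

# lookup tables mapping a raw 0..255 code to its variant code
lbp_variant_lut <- function(variant) {
  codes <- 0:255
  switch(variant,
    basic = codes,
    ri = vapply(codes, min_rotation, integer(1)),
    u2 = {
      uni <- vapply(codes, n_transitions, integer(1)) <= 2
      lut <- integer(256)
      lut[uni] <- match(codes[uni], codes[uni]) - 1L       # 0..57, code order
      lut[!uni] <- sum(uni)                                 # pooled bin 58
      lut
    },
    riu2 = {
      uni <- vapply(codes, n_transitions, integer(1)) <= 2
      nb <- vapply(codes, function(c) sum(bitwAnd(bitwShiftR(c, 0:7), 1L)), integer(1))
      ifelse(uni, nb, 9L)
    },
    stop("variant must be one of basic, ri, u2, riu2"))
}

# distinct bin labels of a variant, in canonical (ascending) order
lbp_code_levels <- function(variant) {
  sort(unique(lbp_variant_lut(variant)))
}

# raw (basic) 8-bit codes of the ROI voxels with full in-grid in-plane
# neighbourhoods; shared by all four variants
lbp_raw_codes <- function(volume, mask, plane) {
  check_volume_mask(volume, mask)
  if (!any(mask)) stop("empty mask")
  d <- dim(volume)
  ax <- lbp_plane_axes(plane)
  co <- mask_coords(mask)  # 0-based (z,y,x)

  # in-plane coordinates must be interior so all 8 neighbours are in-grid
  c1 <- co %*% ax$first   # first-axis coordinate of each voxel
  c2 <- co %*% ax$second
  lim1 <- sum(d * ax$first)   # grid extent along first axis ((z,y,x) order)
  lim2 <- sum(d * ax$second)
  ok <- c1 >= 1 & c1 <= lim1 - 2 & c2 >= 1 & c2 <= lim2 - 2
  co <- co[ok, , drop = FALSE]
  if (nrow(co) == 0) return(integer(0))

  lin0 <- co[, "z"] + d[1] * (co[, "y"] + d[2] * co[, "x"]) + 1L
  centre <- volume[lin0]
  code <- integer(nrow(co))
  for (k in 1:8) {
    off <- lbp_ring[k, "o1"] * ax$first + lbp_ring[k, "o2"] * ax$second  # (z,y,x)
    dlin <- off[1] + d[1] * (off[2] + d[2] * off[3])
    nb <- volume[lin0 + dlin]
    code <- code + bitwShiftL(as.integer(nb >= centre), k - 1L)
  }
  code
}

#' Per-voxel LBP codes in one plane
#'
#' @param volume 3D integer array.
#' @param mask Logical 3D array of the same shape, non-empty.
#' @param plane `"XY"`, `"XZ"` or `"YZ"`.
#' @param variant `"basic"`, `"ri"`, `"u2"` or `"riu2"`.
#' @return Integer vector of variant codes, one per ROI voxel with a
#'   complete in-grid neighbourhood (possibly length 0 for thin ROIs).
#' @export
lbp_plane_codes <- function(volume, mask, plane = c("XY", "XZ", "YZ"),
                            variant = c("basic", "ri", "u2", "riu2")) {
  plane <- match.arg(plane)
  variant <- match.arg(variant)
  code <- lbp_raw_codes(volume, mask, plane)
  if (length(code) == 0) return(integer(0))
  lut <- lbp_variant_lut(variant)
  lut[code + 1L]
}

#' LBP-TOP feature block (48 features)
#'
#' For each of the four code variants, the per-plane code histograms of the
#' XY, XZ and YZ planes are laid side by side into one concatenated
#' histogram (fixed bins: 3 x the variant's code count, zero-filled where a
#' code never occurs), normalized, and summarized with the same 12
#' statistics as the first-order block, treating the concatenated bin index
#' as the value axis. 4 variants x 12 statistics = 48 features,
#' variant-major order.
#'
#' @param volume 3D integer array.
#' @param mask Logical 3D array, non-empty; at least one plane must yield
#'   at least one full-neighbourhood voxel.
#' @param w Peak-window half-width passed to the histogram statistics.
#' @return Named numeric vector of length 48, names `lbp_<variant>_<stat>`.
#' @export
lbp_top_features <- function(volume, mask, w = 5) {
  planes <- c("XY", "XZ", "YZ")
  variants <- c("basic", "ri", "u2", "riu2")
  raw <- lapply(planes, function(p) lbp_raw_codes(volume, mask, p))
  if (all(lengths(raw) == 0)) {
    stop("no ROI voxel has a complete neighbourhood in any plane")
  }
  out <- numeric(0)
  for (v in variants) {
    lut <- lbp_variant_lut(v)
    levels <- sort(unique(lut))
    K <- length(levels)
    counts <- numeric(3 * K)
    for (pi in seq_along(planes)) {
      if (length(raw[[pi]]) > 0) {
        codes <- lut[raw[[pi]] + 1L]
        counts[(pi - 1) * K + seq_len(K)] <-
          tabulate(match(codes, levels), nbins = K)
      }
    }
    s <- histogram_stats(seq_len(3 * K) - 1, counts, w = w)
    out <- c(out, stats::setNames(s, paste0("lbp_", v, "_", names(s))))
  }
  out
}
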