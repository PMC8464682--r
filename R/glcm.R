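#' The 26 three-dimensional co-occurrence directions
#'
#' All displacement vectors with components in \{-1, 0, 1\}, excluding the
#' null vector, in lexicographic order over `(dz, dy, dx)`. Pair tables are
#' directed, so a direction and its opposite are distinct entries — this is
#' what makes the count 26 rather than the 13 symmetry-reduced offsets.
#'
#' @return Integer matrix 26 x 3 with columns `dz, dy, dx`.
#' @export
glcm_directions <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[order(g$dz, g$dy, g$dx), c("dz", "dy", "dx")]
  g <- as.matrix(g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), ])
  rownames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}

glcm_stat_names <- c("autocorrelation", "covariance", "inertia",
                     "abs_inertia", "inv_inertia", "energy", "entropy")

#' Directed gray-level co-occurrence pair table
#'
#' Counts ordered pairs `(I(v), I(v + d))` over all voxels `v` with both
#' `v` and `v + d` inside the ROI, at interpixel distance 1. Raw 16-bit
#' gray values index the table, which is therefore held sparsely — the
#' 65536 x 65536 dense matrix is never materialized, which is what makes
#' full-depth co-occurrence tractable.
#'
#' @param volume 3D integer array.
#' @param mask Logical 3D array of the same shape, non-empty.
#' @param direction Integer length-3 `(dz, dy, dx)`, components in
#'   \{-1, 0, 1\}, not all zero.
#' @return Tibble with columns `i`, `j`, `n` (class `pair_count_table`),
#'   attributes `direction` and `total`; zero rows for ROIs too thin to
#'   contain any pair along `direction`.
#' @export
glcm_pairs <- function(volume, mask, direction) {
  check_volume_mask(volume, mask)
  if (!any(mask)) stop("empty mask")
  direction <- as.integer(direction)
  stopifnot(length(direction) == 3, all(direction %in% -1:1), any(direction != 0))
  d <- dim(volume)
  co <- mask_coords(mask)
  z2 <- co[, "z"] + direction[1]
  y2 <- co[, "y"] + direction[2]
  x2 <- co[, "x"] + direction[3]
  ok <- z2 >= 0 & z2 < d[1] & y2 >= 0 & y2 < d[2] & x2 >= 0 & x2 < d[3]
  lin2 <- z2[ok] + d[1] * (y2[ok] + d[2] * x2[ok]) + 1L
  ok2 <- mask[lin2]
  lin1 <- (co[ok, "z"] + d[1] * (co[ok, "y"] + d[2] * co[ok, "x"]) + 1L)[ok2]
  lin2 <- lin2[ok2]
  tab <- if (length(lin1) == 0) {
    tibble::tibble(i = integer(0), j = integer(0), n = integer(0))
  } else {
    # aggregate ordered pairs on a packed 32-bit key; far cheaper than a
    # grouped summarise at 26 directions per lesion
    key <- as.numeric(volume[lin1]) * 65536 + as.numeric(volume[lin2])
    r <- rle(sort(key))
    tibble::tibble(i = as.integer(r$values %/% 65536),
                   j = as.integer(r$values %% 65536),
                   n = r$lengths)
  }
  attr(tab, "direction") <- direction
  attr(tab, "total") <- sum(tab$n)
  class(tab) <- c("pair_count_table", class(tab))
  tab
}

# the 7 co-occurrence statistics on one normalized sparse pair table
glcm_stats_one <- function(tab) {
  total <- sum(tab$n)
  if (total == 0) {
    return(stats::setNames(rep(0, 7), glcm_stat_names))
  }
  p <- tab$n / total
  i <- as.numeric(tab$i)
  j <- as.numeric(tab$j)
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  dd <- i - j
  c(autocorrelation = sum(i * j * p),
    covariance = sum((i - mu_i) * (j - mu_j) * p),
    inertia = sum(dd^2 * p),
    abs_inertia = sum(abs(dd) * p),
    inv_inertia = sum(p / (1 + dd^2)),
    energy = sum(p^2),
    entropy = -sum(p * log2(p)))
}

#' 3D GLCM feature block (182 features)
#'
#' Seven co-occurrence statistics — autocorrelation, covariance, inertia
#' (contrast), absolute inertia, inverse inertia (homogeneity), energy and
#' entropy — per each of the 26 directed three-dimensional displacements
#' at interpixel distance 1, on the normalized pair probabilities:
#' 26 x 7 = 182 values, direction-major order. A direction whose pair
#' table is empty (thin ROI) contributes seven zeros with a warning.
#'
#' @param volume 3D integer array.
#' @param mask Logical 3D array, non-empty.
#' @return Named numeric vector of length 182, names
#'   `glcm_<dir 01..26>_<stat>`.
#' @export
glcm_features <- function(volume, mask) {
  dirs <- glcm_directions()
  out <- numeric(0)
  n_empty <- 0L
  for (r in seq_len(nrow(dirs))) {
    tab <- glcm_pairs(volume, mask, dirs[r, ])
    if (attr(tab, "total") == 0) n_empty <- n_empty + 1L
    s <- glcm_stats_one(tab)
    out <- c(out, stats::setNames(s, sprintf("glcm_%02d_%s", r, names(s))))
  }
  if (n_empty > 0) {
    warning(sprintf("%d of 26 pair tables empty (thin ROI); their features are 0",
                    n_empty))
  }
  out
}
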