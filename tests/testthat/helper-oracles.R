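# Brute-force oracles, independent of the implementation paths they check.

# Point-in-convex-hull via Caratheodory: x is in conv(S) iff it is a convex
# combination of some <=4 points of S. Solves the barycentric system for
# every 4-subset; only usable for small point sets.
oracle_in_hull <- function(S, x, tol = 1e-9) {
  S <- unique(S)
  n <- nrow(S)
  if (n == 0) return(FALSE)
  for (i in seq_len(n)) {
    if (max(abs(S[i, ] - x)) <= tol) return(TRUE)
  }
  if (n == 1) return(FALSE)
  combs <- utils::combn(n, min(4, n))
  for (c in seq_len(ncol(combs))) {
    idx <- combs[, c]
    A <- rbind(t(S[idx, , drop = FALSE]), rep(1, length(idx)))
    b <- c(x, 1)
    lam <- tryCatch(qr.solve(A, b, tol = 1e-12), error = function(e) NULL)
    if (is.null(lam)) next
    if (all(lam >= -tol) && max(abs(A %*% lam - b)) <= 1e-8) return(TRUE)
  }
  FALSE
}

# Voxelized hull oracle over a whole grid
oracle_hull_mask <- function(mask) {
  S <- edemaradiomics:::mask_coords(mask)
  d <- dim(mask)
  out <- array(FALSE, d)
  for (z in 0:(d[1] - 1)) for (y in 0:(d[2] - 1)) for (x in 0:(d[3] - 1)) {
    out[z + 1, y + 1, x + 1] <- oracle_in_hull(S, c(z, y, x))
  }
  out
}

# Dense GLCM oracle: materialize the co-occurrence matrix over the observed
# gray levels with an explicit double loop over ROI voxels, then compute the
# seven statistics by direct summation.
oracle_glcm <- function(volume, mask, direction) {
  d <- dim(volume)
  lev <- sort(unique(as.vector(volume[mask])))
  M <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    if (!mask[z, y, x]) next
    z2 <- z + direction[1]; y2 <- y + direction[2]; x2 <- x + direction[3]
    if (z2 < 1 || z2 > d[1] || y2 < 1 || y2 > d[2] || x2 < 1 || x2 > d[3]) next
    if (!mask[z2, y2, x2]) next
    a <- as.character(volume[z, y, x]); b <- as.character(volume[z2, y2, x2])
    M[a, b] <- M[a, b] + 1
  }
  tot <- sum(M)
  if (tot == 0) {
    return(c(autocorrelation = 0, covariance = 0, inertia = 0,
             abs_inertia = 0, inv_inertia = 0, energy = 0, entropy = 0))
  }
  P <- M / tot
  iv <- as.numeric(rownames(P))
  auto <- 0; inert <- 0; absin <- 0; invin <- 0; ener <- 0; entr <- 0
  mu_i <- 0; mu_j <- 0
  for (a in seq_along(iv)) for (b in seq_along(iv)) {
    p <- P[a, b]
    mu_i <- mu_i + iv[a] * p; mu_j <- mu_j + iv[b] * p
  }
  covar <- 0
  for (a in seq_along(iv)) for (b in seq_along(iv)) {
    p <- P[a, b]
    if (p == 0) next
    auto <- auto + iv[a] * iv[b] * p
    covar <- covar + (iv[a] - mu_i) * (iv[b] - mu_j) * p
    inert <- inert + (iv[a] - iv[b])^2 * p
    absin <- absin + abs(iv[a] - iv[b]) * p
    invin <- invin + p / (1 + (iv[a] - iv[b])^2)
    ener <- ener + p^2
    entr <- entr - p * log2(p)
  }
  c(autocorrelation = auto, covariance = covar, inertia = inert,
    abs_inertia = absin, inv_inertia = invin, energy = ener, entropy = entr)
}

# Per-pixel LBP bit-arithmetic oracle for one voxel in the XY plane
# (0-based coords), following the documented ring convention.
oracle_lbp_xy <- function(volume, z, y, x) {
  ring <- cbind(dx = c(1, 1, 0, -1, -1, -1, 0, 1),
                dy = c(0, 1, 1, 1, 0, -1, -1, -1))
  centre <- volume[z + 1, y + 1, x + 1]
  code <- 0L
  for (k in 1:8) {
    nb <- volume[z + 1, y + ring[k, "dy"] + 1, x + ring[k, "dx"] + 1]
    if (nb >= centre) code <- code + as.integer(2^(k - 1))
  }
  as.integer(code)
}

# Pairwise-comparison AUC oracle
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# small random blobby mask for property tests (always non-empty)
random_mask <- function(shape, n_seeds = 4, seed = 1) {
  withr::with_seed(seed, {
    m <- array(FALSE, shape)
    idx <- cbind(sample(shape[1], n_seeds, TRUE),
                 sample(shape[2], n_seeds, TRUE),
                 sample(shape[3], n_seeds, TRUE))
    m[idx] <- TRUE
    m
  })
}
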