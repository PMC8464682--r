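test_that("pair tables are directed and count the documented convention", {
  v <- array(0L, c(2, 2, 2))
  v[1, 1, 1] <- 5L
  v[2, 1, 1] <- 9L  # (z,y,x) = (1,0,0) 0-based
  m <- array(FALSE, c(2, 2, 2)); m[1, 1, 1] <- m[2, 1, 1] <- TRUE
  fwd <- glcm_pairs(v, m, c(1, 0, 0))
  expect_equal(nrow(fwd), 1)
  expect_equal(c(fwd$i, fwd$j, fwd$n), c(5, 9, 1))
  bwd <- glcm_pairs(v, m, c(-1, 0, 0))
  expect_equal(c(bwd$i, bwd$j, bwd$n), c(9, 5, 1))
})

test_that("constant ROIs co-occur only on the diagonal", {
  v <- array(7L, c(4, 4, 4))
  m <- array(TRUE, c(4, 4, 4))
  tab <- glcm_pairs(v, m, c(0, 0, 1))
  expect_equal(nrow(tab), 1)
  expect_equal(c(tab$i, tab$j), c(7, 7))
  expect_equal(tab$n, 4 * 4 * 3)
})

test_that("pair totals equal the brute-force neighbour-pair count", {
  set.seed(21)
  for (s in 1:4) {
    v <- array(sample(0:8, 4^3, TRUE), c(4, 4, 4))
    m <- array(sample(c(TRUE, FALSE), 4^3, TRUE), c(4, 4, 4))
    m[2, 2, 2] <- TRUE
    d <- glcm_directions()[sample(26, 1), ]
    got <- attr(glcm_pairs(v, m, d), "total")
    want <- 0
    for (z in 1:4) for (y in 1:4) for (x in 1:4) {
      p2 <- c(z, y, x) + d
      if (m[z, y, x] && all(p2 >= 1 & p2 <= 4) && m[p2[1], p2[2], p2[3]]) {
        want <- want + 1
      }
    }
    expect_equal(got, want)
  }
})

test_that("there are 26 directions: every nonzero {-1,0,1}^3 offset, each direction its own table", {
  d <- glcm_directions()
  expect_equal(dim(d), c(26, 3))
  expect_equal(nrow(unique(d)), 26)
  expect_true(all(d %in% -1:1))
  expect_false(any(rowSums(d == 0) == 3))
  # +/- pairs both present (directed, not symmetry-reduced)
  for (r in seq_len(26)) {
    expect_true(any(colSums(t(d) == -d[r, ]) == 3))
  }
})

test_that("degenerate textures produce the closed-form feature values", {
  v <- array(3L, c(3, 3, 3))
  m <- array(TRUE, c(3, 3, 3))
  f <- glcm_features(v, m)
  for (dd in sprintf("%02d", 1:26)) {
    expect_equal(unname(f[paste0("glcm_", dd, "_autocorrelation")]), 9)
    expect_equal(unname(f[paste0("glcm_", dd, "_covariance")]), 0)
    expect_equal(unname(f[paste0("glcm_", dd, "_inertia")]), 0)
    expect_equal(unname(f[paste0("glcm_", dd, "_inv_inertia")]), 1)
    expect_equal(unname(f[paste0("glcm_", dd, "_energy")]), 1)
    expect_equal(unname(f[paste0("glcm_", dd, "_entropy")]), 0)
  }

  # a single (0,1) pair in one direction
  v2 <- array(0L, c(1, 1, 2)); v2[1, 1, 2] <- 1L
  m2 <- array(TRUE, c(1, 1, 2))
  tab <- glcm_pairs(v2, m2, c(0, 0, 1))
  s <- edemaradiomics:::glcm_stats_one(tab)
  expect_equal(unname(s[c("inertia", "abs_inertia", "inv_inertia",
                          "energy", "entropy", "autocorrelation")]),
               c(1, 1, 0.5, 1, 0, 0))
})

test_that("all 182 features match the dense-matrix oracle on random volumes", {
  set.seed(33)
  for (s in 1:3) {
    v <- array(sample(0:20, 5^3, TRUE), c(5, 5, 5))
    m <- array(TRUE, c(5, 5, 5))
    f <- glcm_features(v, m)
    expect_length(f, 182)
    dirs <- glcm_directions()
    for (r in seq_len(26)) {
      want <- oracle_glcm(v, m, dirs[r, ])
      got <- f[sprintf("glcm_%02d_%s", r, names(want))]
      expect_lt(max(abs(unname(got) - unname(want))), 1e-9)
    }
  }
})

test_that("single-voxel ROIs yield empty tables, zero features and a warning", {
  v <- array(5L, c(3, 3, 3))
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  expect_warning(f <- glcm_features(v, m), "empty")
  expect_true(all(f == 0))
  expect_length(f, 182)
})

test_that("direction-averaged inertia grows with texture noise amplitude", {
  sds <- seq(10, 100, length.out = 10)
  med <- sapply(sds, function(s) {
    mean(sapply(1:5, function(r) {
      v <- generate_texture_volume(c(10, 10, 10), correlation_length = 2,
                                   mean_intensity = 500, noise_sd = s,
                                   seed = 1000 * r + round(s))
      f <- glcm_features(v, array(TRUE, c(10, 10, 10)))
      mean(f[grep("glcm_[0-9]+_inertia$", names(f))])
    }))
  })
  expect_gt(stats::cor(sds, med, method = "spearman"), 0.8)
})
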