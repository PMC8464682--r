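test_that("zero noise gives a constant volume; same seed gives identical volumes", {
  v0 <- generate_texture_volume(c(6, 6, 6), 2, 300, 0, seed = 1)
  expect_true(all(v0 == 300))
  a <- generate_texture_volume(c(8, 8, 8), 1.5, 500, 60, seed = 42)
  b <- generate_texture_volume(c(8, 8, 8), 1.5, 500, 60, seed = 42)
  expect_identical(as.integer(a), as.integer(b))
  c <- generate_texture_volume(c(8, 8, 8), 1.5, 500, 60, seed = 43)
  expect_false(identical(as.integer(a), as.integer(c)))
  expect_error(generate_texture_volume(c(0, 4, 4), 1, 500, 50), "positive")
})

test_that("correlation length raises the lag-1 autocorrelation of the field", {
  lag1 <- function(v) {
    x <- as.numeric(v)
    dim(x) <- dim(v)
    stats::cor(as.vector(x[, , -dim(v)[3]]), as.vector(x[, , -1]))
  }
  ac0 <- sapply(1:10, function(s)
    lag1(generate_texture_volume(c(12, 12, 12), 0, 500, 60, seed = s)))
  ac4 <- sapply(1:10, function(s)
    lag1(generate_texture_volume(c(12, 12, 12), 4, 500, 60, seed = s)))
  expect_gt(mean(ac4), mean(ac0))
  expect_true(all(ac4 > ac0))
})

test_that("ellipsoid masks honour the boundary-inclusive inequality", {
  m <- generate_ellipsoid_mask(c(9, 9, 9), c(4, 4, 4), c(1, 1, 1))
  expect_equal(sum(m), 7)  # centre + 6 face neighbours at distance exactly 1
  co <- edemaradiomics:::mask_coords(m)
  expect_true(all(sqrt(rowSums(sweep(co, 2, c(4, 4, 4))^2)) <= 1 + 1e-12))

  m1 <- generate_ellipsoid_mask(c(9, 9, 9), c(4, 4, 4), c(0.4, 0.4, 0.4))
  expect_equal(which(m1), which(array(seq_len(729), c(9, 9, 9)) == 365))

  mf <- generate_ellipsoid_mask(c(5, 5, 5), c(2, 2, 2), c(50, 50, 50))
  expect_true(all(mf))

  expect_error(generate_ellipsoid_mask(c(5, 5, 5), c(100, 100, 100), c(1, 1, 1)),
               "empty")
})

test_that("cohorts are reproducible and match the configured population structure", {
  spec <- cohort_spec(seed = 7)
  co <- generate_cohort(spec, make_volumes = FALSE)
  expect_equal(nrow(co), 127)
  co2 <- generate_cohort(cohort_spec(seed = 7), make_volumes = FALSE)
  expect_identical(co, co2)

  # IDC fraction within 3 binomial SE of 86.6%
  p <- 1 - 0.134
  se <- sqrt(p * (1 - p) / 127)
  expect_lt(abs(mean(co$histological_type == "IDC") - p), 3 * se)

  big <- generate_cohort(cohort_spec(n_lesions = 2000, seed = 11),
                         make_volumes = FALSE)
  prev <- cohort_spec()$label_prevalences
  for (l in names(prev)) {
    se <- sqrt(prev[[l]] * (1 - prev[[l]]) / 2000)
    expect_lt(abs(mean(big[[paste0("label_", l)]]) - prev[[l]]), 3 * se)
  }
  et <- table(factor(big$edema_type, levels = 1:4)) / 2000
  for (k in 1:4) {
    p0 <- cohort_spec()$edema_type_probs[k]
    expect_lt(abs(et[k] - p0), 3 * sqrt(p0 * (1 - p0) / 2000))
  }
})

test_that("volumes composite a brighter edema texture inside the mask", {
  spec <- cohort_spec(n_lesions = 3, grid_shape = c(20, 20, 20), seed = 5)
  co <- generate_cohort(spec)
  for (i in 1:3) {
    v <- co$volume[[i]]; m <- co$mask[[i]]
    expect_identical(dim(v), dim(m))
    expect_true(sum(m) > 0)
    expect_gt(mean(v[m]), mean(v[!m]))  # edema reads bright on T2
    expect_true(all(v >= 0 & v <= 65535))
  }
  co2 <- generate_cohort(cohort_spec(n_lesions = 3, grid_shape = c(20, 20, 20),
                                     seed = 5))
  expect_identical(as.integer(co$volume[[2]]), as.integer(co2$volume[[2]]))
})

test_that("a planted texture effect shifts GLCM inertia between classes", {
  spec <- cohort_spec(n_lesions = 24, grid_shape = c(20, 20, 20),
                      label_prevalences = c(histology = 0.134, grading = 0.5,
                                            er = 0.795, pgr = 0.362, ki67 = 0.661),
                      texture_effect = c(histology = 0, grading = 1.5,
                                         er = 0, pgr = 0, ki67 = 0),
                      seed = 19)
  co <- generate_cohort(spec)
  inertia <- sapply(seq_len(nrow(co)), function(i) {
    f <- glcm_features(co$volume[[i]], co$mask[[i]])
    mean(f[grep("glcm_[0-9]+_inertia$", names(f))])
  })
  y <- co$label_grading
  expect_true(min(table(y)) >= 2)
  # larger noise amplitude -> rougher edema texture -> higher inertia
  expect_gt(mean(inertia[y == 1]), mean(inertia[y == 0]))
  expect_lt(stats::wilcox.test(inertia[y == 1], inertia[y == 0])$p.value, 0.05)
})

test_that("spec validation rejects malformed populations", {
  expect_error(cohort_spec(n_lesions = 1))
  expect_error(cohort_spec(edema_type_probs = c(0.5, 0.2, 0.2, 0.2)))
  expect_error(cohort_spec(label_prevalences = c(histology = 0, grading = 0.5,
                                                 er = 0.5, pgr = 0.5, ki67 = 0.5)))
})
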