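cheap_select <- function(...) select_config(trees = 25, internal_folds = 3, ...)

test_that("AUC equals the pairwise Mann-Whitney oracle, ties included", {
  set.seed(17)
  for (s in 1:6) {
    n <- sample(10:50, 1)
    y <- c(0, 1, sample(0:1, n - 2, TRUE))
    sc <- sample(seq(0, 1, by = 0.1), n, TRUE)  # heavy ties
    expect_equal(auc_mann_whitney(sc, y), oracle_auc(sc, y))
  }
  expect_error(auc_mann_whitney(1:3, c(1, 1, 1)), "both classes")
})

test_that("stratified folds partition the data and balance classes", {
  y <- c(rep(1, 20), rep(0, 80))
  f <- stratified_folds(y, 10, seed = 3)
  expect_equal(sort(unique(f)), 1:10)
  expect_equal(as.vector(table(f)), rep(10L, 10))
  for (k in 1:10) expect_equal(sum(y[f == k]), 2)
  expect_warning(stratified_folds(c(rep(1, 3), rep(0, 40)), 10, 1), "shrinking")
  expect_error(stratified_folds(c(1, rep(0, 10)), 5, 1), "at least 2")
})

test_that("best-first selection recovers a planted feature", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 100
    y <- rep(0:1, each = n / 2)
    x <- as.data.frame(matrix(rnorm(n * 8), n, 8))
    names(x) <- paste0("f", 1:8)
    x$oracle <- y + rnorm(n, 0, 0.05)
    sel <- best_first_select(x, y, cheap_select(), seed = s)
    if ("oracle" %in% sel$features) hits <- hits + 1
  }
  expect_gte(hits, 19)  # >= 95% of 20 seeds
})

test_that("duplicate features add no merit: one copy selected", {
  set.seed(5)
  n <- 60
  y <- rep(0:1, each = n / 2)
  base <- y + rnorm(n, 0, 0.3)
  x <- data.frame(a = base, b = base, c = base, d = base)
  sel <- best_first_select(x, y, cheap_select(), seed = 2)
  expect_length(sel$features, 1)
  expect_equal(sel$features, "a")  # ties resolve to the earlier feature
})

test_that("with no informative feature the selected merit stays near chance", {
  # the winning merit is a maximum over noisy internal-CV AUCs, so it sits
  # slightly above chance; at n = 200 the optimism stays within the band
  merits <- sapply(1:5, function(s) {
    set.seed(100 + s)
    x <- as.data.frame(matrix(rnorm(200 * 6), 200, 6))
    y <- rep(0:1, each = 100)
    best_first_select(x, y, select_config(trees = 25, internal_folds = 5),
                      seed = s)$merit
  })
  expect_lt(abs(mean(merits) - 0.5), 0.1)
})

test_that("selection refuses degenerate single-class input", {
  x <- data.frame(a = rnorm(10))
  expect_error(best_first_select(x, rep(1, 10), cheap_select()), "single-class")
})

test_that("a perfectly separating feature yields AUC 1 and accuracy 1", {
  set.seed(1)
  n <- 60
  y <- rep(0:1, each = n / 2)
  x <- data.frame(sig = y * 2 + rnorm(n, 0, 0.05),
                  noise = rnorm(n))
  ev <- crossval_evaluate(x, y, eval_config(n_folds = 5, trees = 50,
                                            select = cheap_select()),
                          seed = 4)
  expect_equal(ev$auc, 1)
  expect_equal(unname(ev$metrics["accuracy"]), 1)
})

test_that("metric identities hold exactly against the stored confusion matrix", {
  set.seed(6)
  n <- 80
  y <- rbinom(n, 1, 0.4)
  x <- data.frame(a = y + rnorm(n, 0, 1), b = rnorm(n))
  ev <- crossval_evaluate(x, y, eval_config(n_folds = 5, trees = 50,
                                            select_inside_folds = FALSE),
                          seed = 9)
  cm <- as.list(ev$confusion)
  expect_equal(sum(unlist(cm)), n)
  expect_equal(unname(ev$metrics["accuracy"]), (cm$tp + cm$tn) / n)
  expect_equal(unname(ev$metrics["sensitivity"]), cm$tp / (cm$tp + cm$fn))
  expect_equal(unname(ev$metrics["specificity"]), cm$tn / (cm$tn + cm$fp))
  expect_equal(unname(ev$metrics["ppv"]), cm$tp / (cm$tp + cm$fp))
  expect_equal(unname(ev$metrics["npv"]), cm$tn / (cm$tn + cm$fn))
})

test_that("every lesion is predicted exactly once, in its own held-out fold", {
  set.seed(2)
  n <- 50
  y <- rbinom(n, 1, 0.5); y[1:2] <- c(0, 1)
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  ev <- crossval_evaluate(x, y, eval_config(n_folds = 5, trees = 30,
                                            select_inside_folds = FALSE),
                          seed = 7)
  expect_equal(sort(ev$predictions$row), 1:n)
  expect_equal(ev$predictions$fold, as.integer(ev$folds))
  expect_equal(length(ev$selected), 5)
})

test_that("identical cohort, config and seed reproduce the report exactly", {
  set.seed(3)
  n <- 60
  y <- rbinom(n, 1, 0.45); y[1:2] <- c(0, 1)
  x <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  cfg <- eval_config(n_folds = 5, trees = 40, select = cheap_select())
  e1 <- crossval_evaluate(x, y, cfg, seed = 12)
  e2 <- crossval_evaluate(x, y, cfg, seed = 12)
  expect_identical(e1$predictions, e2$predictions)
  expect_identical(e1$selected, e2$selected)
  expect_identical(glance(e1), glance(e2))
})

test_that("an uninformative imbalanced label collapses to the all-negative classifier", {
  set.seed(8)
  n <- 100
  y <- c(rep(1, 11), rep(0, 89))  # 11% positives
  x <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  ev <- crossval_evaluate(x, y, eval_config(n_folds = 5, trees = 100,
                                            select_inside_folds = FALSE),
                          seed = 21)
  expect_equal(unname(ev$metrics["sensitivity"]), 0)
  expect_equal(unname(ev$metrics["specificity"]), 1)
  expect_equal(unname(ev$metrics["ppv"]), 0)           # 0/0 convention
  expect_true("ppv" %in% ev$degenerate)
  expect_equal(unname(ev$metrics["npv"]), 0.89)        # prevalence complement
  expect_equal(unname(ev$metrics["accuracy"]), 0.89)
})

test_that("tidy/glance/autoplot expose the report in standard shapes", {
  set.seed(4)
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  x <- data.frame(a = y + rnorm(40), b = rnorm(40))
  ev <- crossval_evaluate(x, y, eval_config(n_folds = 4, trees = 30,
                                            select_inside_folds = FALSE),
                          seed = 2, label = "demo")
  td <- tidy(ev)
  expect_equal(names(td), c("label", "configuration", "metric", "value"))
  expect_equal(nrow(td), 6)
  gl <- glance(ev)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$label, "demo")
  p <- ggplot2::autoplot(ev)
  expect_s3_class(p, "ggplot")
})
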