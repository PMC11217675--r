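# a feature table of two well-separated Gaussian blobs in feature space
blobTable <- function(n = 60, delta = 8, seed = 1) {
  withr::with_seed(seed, {
    feat <- rbind(
      matrix(rnorm(n * 9), n, 9),
      matrix(rnorm(n * 9, mean = delta), n, 9)
    )
    colnames(feat) <- paste0("F", 1:9)
    data.frame(
      ID = paste0("r", seq_len(2 * n)),
      feat,
      Class = rep(c(0L, 1L), each = n)
    )
  })
}

test_that("z-normalization follows the sample-sd convention, train stats only", {
  sc <- zscoreFit(data.frame(F1 = c(1, 2, 3)), columns = "F1")
  expect_equal(sc$mean[["F1"]], 2)
  expect_equal(sc$sd[["F1"]], 1) # sample sd (n - 1)
  expect_equal(zscoreApply(sc, data.frame(F1 = c(1, 2, 3)))$F1, c(-1, 0, 1))
  # test rows are scaled with TRAINING statistics, not their own
  expect_equal(zscoreApply(sc, data.frame(F1 = c(4, 6)))$F1, c(2, 4))
  expect_error(zscoreFit(data.frame(F1 = c(2, 2, 2)), columns = "F1"), "constant.*F1")
  # applying twice is not idempotent: mean/sd refer to the original scale
  once <- zscoreApply(sc, data.frame(F1 = c(1, 2, 3)))
  twice <- zscoreApply(sc, once)
  expect_false(isTRUE(all.equal(once$F1, twice$F1)))
})

test_that("positive rescaling of a column leaves z-scores unchanged", {
  withr::with_seed(3, tab <- data.frame(F1 = rnorm(50, 10, 3)))
  z1 <- zscoreApply(zscoreFit(tab, "F1"), tab)$F1
  tab2 <- data.frame(F1 = tab$F1 * 7.3)
  z2 <- zscoreApply(zscoreFit(tab2, "F1"), tab2)$F1
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("all three models separate distant blobs perfectly", {
  tab <- blobTable()
  for (m in c("svm_rbf", "random_forest", "ann")) {
    r <- trainEval(tab, m, seed = 5)
    expect_equal(metrics(r)$accuracy, 1)
    expect_equal(auc(r), 1)
    expect_equal(metrics(r)$sensitivity, 1)
    expect_equal(metrics(r)$specificity, 1)
  }
})

test_that("label-shuffled tables score at chance", {
  tab <- blobTable(n = 100, delta = 0, seed = 7) # no signal at all
  r <- trainEval(tab, "svm_rbf", seed = 9)
  nTest <- sum(confusion(r))
  expect_lt(abs(metrics(r)$accuracy - 0.5), 3 * sqrt(0.25 / nTest) + 0.05)
  expect_lt(abs(auc(r) - 0.5), 0.2)
})

test_that("evaluation is deterministic given the seed", {
  tab <- blobTable(n = 40, delta = 2, seed = 11)
  r1 <- trainEval(tab, "svm_rbf", seed = 13)
  r2 <- trainEval(tab, "svm_rbf", seed = 13)
  expect_identical(metrics(r1), metrics(r2))
  expect_identical(predictions(r1), predictions(r2))
  expect_identical(confusion(r1), confusion(r2))
})

test_that("report metrics recompute exactly from the confusion matrix", {
  tab <- blobTable(n = 50, delta = 1.5, seed = 17)
  r <- trainEval(tab, "random_forest", seed = 19)
  cm <- confusion(r)
  tp <- cm["1", "1"]
  tn <- cm["0", "0"]
  fp <- cm["1", "0"]
  fn <- cm["0", "1"]
  expect_equal(metrics(r)$sensitivity, tp / (tp + fn))
  expect_equal(metrics(r)$specificity, tn / (tn + fp))
  expect_equal(metrics(r)$accuracy, (tp + tn) / sum(cm))
  ci <- binom.test(tp + tn, sum(cm))$conf.int
  expect_equal(metrics(r)$accuracyCI, as.numeric(ci))
  # ROC points are monotone in both coordinates
  rp <- rocPoints(r)
  expect_true(all(diff(rp$FPR) >= 0))
  expect_true(all(diff(rp$TPR) >= 0))
})

test_that("trapezoidal AUC equals the normalized Mann-Whitney statistic", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(rocAuc(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 1, 0))$auc, 0.5) # ties half-credit
  expect_equal(rocAuc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))$auc, 0)
  expect_error(rocAuc(1:3, c(1, 1, 1)), "both classes")
  withr::with_seed(23, {
    for (i in 1:1000) {
      n <- sample(10:60, 1)
      sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # heavy ties
      lb <- sample(0:1, n, replace = TRUE)
      if (length(unique(lb)) < 2) next
      expect_lt(abs(rocAuc(sc, lb)$auc - oracleAuc(sc, lb)), 1e-9)
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(29, {
    sc <- rnorm(200)
    lb <- rep(0:1, 100)
    sc[lb == 1] <- sc[lb == 1] + 1
  })
  ours <- rocAuc(sc, lb)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE, direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("null AUC concentrates around one half", {
  withr::with_seed(31, {
    sc <- runif(1000)
    lb <- sample(rep(0:1, 500))
  })
  expect_lt(abs(rocAuc(sc, lb)$auc - 0.5), 0.05)
})

test_that("repeated evaluation isolates control-sampling variability", {
  spec <- compositionSpec(gc = 37, gpcFold = 1.5, ccggFold = 0.7)
  pos <- markovGenerate(spec, 30, seed = 37, lengths = rep(300L, 30), prefix = "pos")
  bg <- compositionSpec(gc = 42)
  sampler <- function(seed) {
    markovGenerate(bg, 30, seed = seed, lengths = rep(300L, 30), prefix = "ctl")
  }
  res <- repeatedEval(pos, sampler, nSubsets = 3, model = "svm_rbf", seed = 41)
  expect_length(res$accuracies, 3)
  expect_equal(res$mean, mean(res$accuracies))
  # forcing identical subsets removes all variability
  fixedSet <- sampler(1)
  res0 <- repeatedEval(pos, function(seed) fixedSet, nSubsets = 2, seed = 41)
  expect_identical(res0$sd, 0)
})
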