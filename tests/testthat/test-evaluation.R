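test_that("confusion metrics recover the standard definitions", {
  truth <- rep(c(TRUE, FALSE), each = 10)
  perfect <- confusionMetrics(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  inverted <- confusionMetrics(!truth, truth)
  expect_equal(inverted$accuracy, 0)
  expect_equal(inverted$sensitivity, 0)
  expect_equal(inverted$specificity, 0)

  # 91/9 pattern in both classes: all three metrics at 0.91
  truth2 <- rep(c(TRUE, FALSE), each = 100)
  dec2 <- c(rep(TRUE, 91), rep(FALSE, 9), rep(TRUE, 9), rep(FALSE, 91))
  m <- confusionMetrics(dec2, truth2)
  expect_equal(m$accuracy, 0.91)
  expect_equal(m$sensitivity, 0.91)
  expect_equal(m$specificity, 0.91)
  expect_equal(m$ci, qnorm(0.975) * sqrt(0.91 * 0.09 / 200))

  oneClass <- confusionMetrics(c(TRUE, FALSE), c(TRUE, TRUE))
  expect_true(is.na(oneClass$specificity))
  expect_false(is.na(oneClass$sensitivity))
})

test_that("ROC/AUC equals the Mann-Whitney statistic, ties included", {
  set.seed(1)
  for (i in 1:30) {
    n <- sample(20:80, 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    scores <- sample(1:10, n, replace = TRUE) + rnorm(n, sd = 0.001 *
                                                        (i %% 2))
    auc <- rocAuc(scores, truth)$auc
    x <- scores[truth]
    y <- scores[!truth]
    u <- sum(vapply(x, function(xi)
      sum(xi > y) + 0.5 * sum(xi == y), numeric(1)))
    expect_equal(auc, u / (length(x) * length(y)), tolerance = 1e-12)
  }
})

test_that("ROC endpoints, separated and null cases behave", {
  truth <- rep(c(TRUE, FALSE), each = 50)
  sep <- rocAuc(c(rnorm(50, 10), rnorm(50, -10)), truth)
  expect_equal(sep$auc, 1)
  expect_equal(sep$rocPoints$fpr[1], 0)
  expect_equal(sep$rocPoints$tpr[nrow(sep$rocPoints)], 1)
  expect_true(all(diff(sep$rocPoints$tpr) >= 0))

  set.seed(2)
  null <- rocAuc(rnorm(2000), sample(c(TRUE, FALSE), 2000, replace = TRUE))
  expect_gt(null$auc, 0.47)
  expect_lt(null$auc, 0.53)

  expect_warning(flat <- rocAuc(rep(1, 100), truth), "constant")
  expect_equal(flat$auc, 0.5)
  expect_error(rocAuc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(3)
  p <- runif(200)
  truth <- rbinom(200, 1, 1 - p) > 0   # smaller p more response-like
  a1 <- rocAuc(1 - p, truth)$auc
  a2 <- rocAuc(-log(p), truth)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("DeLong self-comparison is exactly one half", {
  set.seed(4)
  scores <- rnorm(100)
  truth <- rep(c(TRUE, FALSE), 50)
  res <- delongTest(scores, scores, truth)
  expect_identical(res$p.value, 0.5)
})

test_that("a perfect scorer beats a random one decisively", {
  set.seed(5)
  truth <- rep(c(TRUE, FALSE), each = 200)
  perfect <- as.numeric(truth) + rnorm(400, sd = 0.01)
  random <- rnorm(400)
  res <- delongTest(perfect, random, truth)
  expect_lt(res$p.value, 0.001)
  # and the two one-sided orientations are complementary
  res2 <- delongTest(random, perfect, truth)
  expect_equal(res$p.value + res2$p.value, 1, tolerance = 1e-12)
})

test_that("DeLong agrees with the pROC reference implementation", {
  set.seed(6)
  truth <- rep(c(TRUE, FALSE), each = 60)
  a <- as.numeric(truth) * 0.8 + rnorm(120)
  b <- as.numeric(truth) * 0.4 + rnorm(120)
  mine <- delongTest(a, b, truth, alternative = "two.sided")
  ra <- pROC::roc(truth, a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(truth, b, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-6)
  expect_equal(unname(mine$estimate["aucA"]), as.numeric(pROC::auc(ra)),
               tolerance = 1e-12)
  one <- delongTest(a, b, truth)
  refG <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE,
                         alternative = "greater")
  expect_equal(one$p.value, refG$p.value, tolerance = 1e-6)
})

test_that("Fleiss' kappa matches a from-definition oracle and is invariant", {
  set.seed(7)
  ratings <- matrix(sample(c(TRUE, FALSE), 30, replace = TRUE), 10, 3)
  k <- fleissKappa(ratings)
  expect_equal(k, fleissOracle(ratings), tolerance = 1e-12)
  expect_equal(fleissKappa(ratings[, c(3, 1, 2)]), k, tolerance = 1e-14)
  expect_equal(fleissKappa(ratings[sample(10), ]), k, tolerance = 1e-14)
})

test_that("Fleiss' kappa hits its anchor cases", {
  agree <- cbind(rep(c(TRUE, FALSE), 5), rep(c(TRUE, FALSE), 5),
                 rep(c(TRUE, FALSE), 5))
  expect_equal(fleissKappa(agree), 1)

  set.seed(8)
  random <- matrix(sample(c(TRUE, FALSE), 3000, replace = TRUE), 1000, 3)
  expect_lt(abs(fleissKappa(random)), 0.05)

  unanimous <- matrix(TRUE, 10, 3)
  expect_warning(k <- fleissKappa(unanimous), "undefined")
  expect_true(is.na(k))
})

test_that("the rater-agreement report computes kappa and FPR vs consensus", {
  ids <- sprintf("r%02d", 1:20)
  set.seed(9)
  wide <- cbind(e1 = rep(c(TRUE, FALSE), each = 10),
                e2 = rep(c(TRUE, FALSE), each = 10),
                e3 = c(rep(TRUE, 8), rep(FALSE, 12)))
  labels <- data.frame(
    recording_id = rep(ids, 3),
    rater_id = rep(c("e1", "e2", "e3"), each = 20),
    round = 1L,
    response_present = as.vector(wide))
  consensus <- setNames(rep(c(TRUE, FALSE), each = 10), ids)
  freqs <- setNames(rep(c(500, 1000), 10), ids)
  rep_ <- raterAgreement(labels, consensus = consensus, frequencies = freqs)
  expect_equal(rep_$kappa, fleissOracle(wide), tolerance = 1e-12)
  expect_equal(unname(rep_$falsePositiveRate["e1"]), 0)
  expect_equal(unname(rep_$falsePositiveRate["e3"]), 0)
  expect_length(rep_$kappaByFrequency, 2)
})
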