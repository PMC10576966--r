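# F-score ranking, NearMiss, metrics and model evaluation.

sepData <- function(n = 30, d = 4, gap = 8, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n * d), ncol = d)
  x[seq_len(n), 1] <- x[seq_len(n), 1] + gap
  list(x = x, y = rep(c("positive", "negative"), each = n))
}

test_that("fScores reproduces the hand-computed toy value", {
  x <- matrix(c(0, 2, 4, 6))
  r <- fScores(x, c(1, 1, 0, 0))
  expect_equal(r@scores, 2)
  # constant feature scores 0 by the zero-denominator convention
  r2 <- fScores(cbind(x, rep(7, 4)), c(1, 1, 0, 0))
  expect_equal(r2@scores[2], 0)
  expect_equal(r2@order, c(1L, 2L))
  # label swap leaves scores unchanged
  r3 <- fScores(x, c(0, 0, 1, 1))
  expect_equal(r3@scores, r@scores)
  expect_error(fScores(x, c(1, 1, 1, 1)), "class")
})

test_that("fScores matches a naive reimplementation on random data", {
  set.seed(7)
  x <- matrix(rnorm(40 * 6), ncol = 6)
  y <- rep(c(1, 0), each = 20)
  r <- fScores(x, y)
  naive <- vapply(seq_len(6), function(i) {
    xp <- x[y == 1, i]; xn <- x[y == 0, i]
    num <- (mean(xp) - mean(x[, i]))^2 + (mean(xn) - mean(x[, i]))^2
    num / (var(xp) + var(xn))
  }, 1.0)
  expect_equal(r@scores, naive, tolerance = 1e-12)
  expect_equal(r@order, order(-naive))
})

test_that("nearMiss keeps the majority samples closest to the minority", {
  # 1-D toy: minority {0}, majority {1, 5, 10}
  x <- matrix(c(0, 1, 5, 10))
  kept <- nearMiss(x, c("positive", "negative", "negative", "negative"))
  expect_equal(kept, c(1L, 2L))
  # balanced input is untouched
  xb <- matrix(rnorm(20), ncol = 2)
  expect_equal(nearMiss(xb, rep(c(1, 0), each = 5)), 1:10)
})

test_that("nearMiss always balances to 2 x |minority|", {
  set.seed(5)
  for (i in 1:10) {
    nMin <- sample(3:15, 1)
    nMaj <- nMin + sample(1:40, 1)
    x <- matrix(rnorm((nMin + nMaj) * 5), ncol = 5)
    y <- c(rep("positive", nMin), rep("negative", nMaj))
    kept <- nearMiss(x, y)
    expect_length(kept, 2 * nMin)
    expect_equal(sum(y[kept] == "negative"), nMin)
    expect_true(all(which(y == "positive") %in% kept))
  }
})

test_that("confusionMetrics matches the closed forms", {
  expect_equal(confusionMetrics(5, 7, 0, 0),
               c(sp = 1, sn = 1, acc = 1, mcc = 1))
  m <- confusionMetrics(9, 8, 2, 1)
  expect_equal(unname(m["sn"]), 0.9)
  expect_equal(unname(m["sp"]), 0.8)
  expect_equal(unname(m["acc"]), 0.85)
  expect_equal(unname(m["mcc"]), 70 / sqrt(9900))
  # degenerate: everything predicted positive
  m2 <- confusionMetrics(10, 0, 5, 0)
  expect_equal(unname(m2["mcc"]), 0)
  expect_equal(unname(m2["sp"]), 0)
  expect_error(confusionMetrics(0, 0, 0, 0), "zero")
})

test_that("rocAuc follows the rank formulation with tie handling", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_equal(rocAuc(c(5, 6, 7, 8), c(0, 0, 1, 1)), 1)
  expect_equal(rocAuc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(rocAuc(1:4, rep(1, 4)), "class")
  set.seed(11)
  s <- rnorm(40); y <- rbinom(40, 1, 0.5)
  y[1:2] <- c(0, 1)
  expect_equal(rocAuc(s, y) + rocAuc(-s, y), 1)
  # agree with an established implementation
  expect_equal(rocAuc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("rocCurve starts at (0,0) and ends at (1,1)", {
  rc <- rocCurve(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1)
  expect_equal(rc$tpr[nrow(rc)], 1)
})

test_that("crossValidate is perfect on well-separated classes", {
  d <- sepData(n = 15, gap = 10, seed = 3)
  for (kind in c("gbc", "rfc")) {
    r <- crossValidate(d$x, d$y, modelConfig(kind), k = 5, seed = 2)
    expect_equal(r@acc, 1, info = kind)
    expect_equal(r@mcc, 1, info = kind)
    expect_equal(r@auc, 1, info = kind)
  }
  # SVC ranks perfectly; its Platt probabilities can miss the 0.5
  # threshold on folds this small
  rs <- crossValidate(d$x, d$y, modelConfig("svc"), k = 5, seed = 2)
  expect_gte(rs@auc, 0.99)
  expect_gte(rs@acc, 0.9)
  expect_error(crossValidate(d$x, d$y, k = 16), "class size")
  # per-fold breakdown covers every fold
  r <- crossValidate(d$x, d$y, modelConfig("gbc"), k = 5, seed = 2)
  expect_equal(r@folds$fold, 1:5)
  expect_equal(r@tp + r@tn + r@fp + r@fn, 30)
})

test_that("independentTest reports one line per metric with mean and sd", {
  d <- sepData(n = 12, gap = 10, seed = 4)
  it <- independentTest(d$x, d$y, modelConfig("gbc"), testSize = 0.25,
                        repeats = 3, seed = 9)
  expect_length(it$reports, 3)
  expect_equal(it$reports[[1]]@mcc, 1)
  expect_equal(it$summary$metric, c("sp", "sn", "acc", "mcc", "auc"))
  expect_equal(it$summary$mean, rep(1, 5))
  expect_equal(it$summary$sd, rep(0, 5))
})

test_that("incrementalSelection finds a single perfect feature at m = 1", {
  set.seed(6)
  y <- rep(c("positive", "negative"), each = 12)
  x <- cbind(ifelse(y == "positive", 1, 0) + rnorm(24, sd = 0.01),
             matrix(rnorm(24 * 4), ncol = 4))
  r <- fScores(x, y)
  expect_equal(r@order[1], 1L)
  sel <- incrementalSelection(x, y, r, modelConfig("gbc"), k = 4,
                              seed = 1)
  expect_equal(sel$curve$mcc[1], 1)
  expect_equal(sel$optimalM, 1)
  expect_equal(sel$optimalFeatures, 1L)
})

test_that("incrementalSelection recovers two informative features", {
  hits <- 0
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20
    y <- rep(c("positive", "negative"), each = n)
    x <- matrix(rnorm(2 * n * 10), ncol = 10)
    # moderate shifts: neither informative feature separates alone, so
    # the MCC-optimal prefix has to reach past both
    x[y == "positive", c(3, 7)] <- x[y == "positive", c(3, 7)] + 1.5
    r <- fScores(x, y)
    sel <- incrementalSelection(x, y, r, modelConfig("gbc"), k = 4,
                                seed = seed)
    if (all(c(3, 7) %in% sel$optimalFeatures)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
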