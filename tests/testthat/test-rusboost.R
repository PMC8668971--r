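test_that("random undersampling balances classes without touching the minority", {
  d <- data.frame(f1 = rnorm(14))
  y <- rep(c("maj", "min"), c(10, 4))
  out <- randomUndersample(d, y, seed = 50)
  expect_equal(unname(table(out$labels)["maj"]), 4L)
  expect_equal(unname(table(out$labels)["min"]), 4L)
  expect_true(all(which(y == "min") %in% out$indices))
  expect_true(all(out$indices[out$labels == "maj"] %in% which(y == "maj")))
  expect_equal(sum(out$weights), 1, tolerance = 1e-12)

  # already balanced: nothing removed
  yb <- rep(c("a", "b"), each = 5)
  outB <- randomUndersample(data.frame(f1 = rnorm(10)), yb, seed = 1)
  expect_setequal(outB$indices, 1:10)

  # deterministic for a fixed seed, variable across seeds
  y2 <- rep(c("maj", "min"), c(60, 5))
  d2 <- data.frame(f1 = rnorm(65))
  i1 <- randomUndersample(d2, y2, seed = 7)$indices
  i2 <- randomUndersample(d2, y2, seed = 7)$indices
  expect_identical(i1, i2)
  draws <- vapply(1:8, function(s)
    paste(randomUndersample(d2, y2, seed = s)$indices, collapse = ","),
    character(1))
  expect_gt(length(unique(draws)), 1)

  expect_error(randomUndersample(d, rep("maj", 14)), "both classes")
})

test_that("boosting separates separable data and honors its weight contract", {
  d <- separableData(60, gap = 3, seed = 51)
  model <- trainRUSBoost(d[, 1:2], d$y, iterations = 50, seed = 51)
  acc <- mean(predict(model, d[, 1:2]) == d$y)
  expect_gte(acc, 0.95)

  h <- model@history
  expect_true(all(h$nMinorityResampled == h$nMajorityResampled))
  expect_true(all(abs(h$weightSum - 1) <= 1e-9))
  expect_true(all(h$minWeight >= 0))
  expect_true(all(h$pseudoLoss < 0.5))
  expect_true(all(is.finite(voteWeights(model))))
})

test_that("a single-iteration ensemble is its weak hypothesis", {
  d <- separableData(40, gap = 3, seed = 52)
  model <- trainRUSBoost(d[, 1:2], d$y, iterations = 1, seed = 52)
  expect_length(weakHypotheses(model), 1)
  single <- predict(weakHypotheses(model)[[1]],
                    newdata = d[, 1:2], type = "class")
  expect_equal(as.character(predict(model, d[, 1:2])),
               as.character(single))

  # identical rows get identical predictions
  same <- d[rep(1, 6), 1:2]
  expect_length(unique(as.character(predict(model, same))), 1)
})

test_that("training error is non-increasing in ensemble size on separable data", {
  sizes <- c(1, 5, 25, 50)
  errs <- matrix(NA_real_, 10, length(sizes))
  for (s in 1:10) {
    d <- separableData(60, gap = 2, seed = 600 + s)
    full <- trainRUSBoost(d[, 1:2], d$y, iterations = 50, seed = 600 + s)
    for (k in seq_along(sizes)) {
      p <- min(sizes[k], length(full@hypotheses))
      sub <- new("RUSBoostModel", hypotheses = full@hypotheses[1:p],
                 voteWeights = full@voteWeights[1:p],
                 classes = full@classes,
                 minorityClass = full@minorityClass,
                 weakLearnerSpec = full@weakLearnerSpec,
                 history = full@history[1:p, ])
      errs[s, k] <- mean(predict(sub, d[, 1:2]) != d$y)
    }
  }
  med <- apply(errs, 2, median)
  expect_true(all(diff(med) <= 1e-12))
})

test_that("label-permuted features yield chance-level cross-validated accuracy", {
  set.seed(53)
  n <- 60
  d <- data.frame(f1 = rnorm(n), f2 = rnorm(n))
  y <- rep(c("maj", "min"), c(40, 20))   # labels carry no signal
  rep10 <- stratifiedKFoldCV(d, y, k = 10, iterations = 30, seed = 53)
  majority <- 40 / n
  se <- sqrt(majority * (1 - majority) / n)
  expect_lte(rep10$accuracy, majority + 3 * se)
})

test_that("on balanced data RUSBoost matches plain boosting within noise", {
  accR <- accB <- numeric(10)
  for (s in 1:10) {
    set.seed(700 + s)
    n <- 60
    x <- data.frame(f1 = c(rnorm(n / 2), rnorm(n / 2) + 1.2),
                    f2 = rnorm(n))
    y <- rep(c("a", "b"), each = n / 2)
    fold <- rep_len(1:5, n)[sample(n)]
    prR <- prB <- character(n)
    for (f in 1:5) {
      tr <- fold != f
      mR <- trainRUSBoost(x[tr, ], y[tr], iterations = 25, seed = 700 + s)
      set.seed(700 + s)
      mB <- oracleAdaBoostM2(x[tr, ], y[tr], iterations = 25)
      prR[!tr] <- as.character(predict(mR, x[!tr, ]))
      prB[!tr] <- as.character(predictOracleBoost(mB, x[!tr, ]))
    }
    accR[s] <- mean(prR == y)
    accB[s] <- mean(prB == y)
  }
  se <- sd(accR - accB) / sqrt(10)
  expect_lte(abs(mean(accR) - mean(accB)), max(3 * se, 0.05))
})

test_that("metrics reproduce the confusion-count formulas", {
  cm <- matrix(c(9, 1, 1, 9), 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  rep <- computeMetrics(cm)
  expect_equal(rep$accuracy, 0.9)
  expect_equal(rep$perClass$precision, c(0.9, 0.9))
  expect_equal(rep$perClass$recall, c(0.9, 0.9))
  expect_equal(rep$perClass$f_score, c(0.9, 0.9))

  # random counts against independent formula evaluation
  set.seed(54)
  for (r in 1:10) {
    cm <- matrix(rpois(4, 20) + 1, 2,
                 dimnames = list(c("x", "y"), c("x", "y")))
    rep <- computeMetrics(cm)
    tp <- cm[1, 1]; fp <- cm[2, 1]; fn <- cm[1, 2]
    expect_equal(rep$perClass$precision[1], tp / (tp + fp))
    expect_equal(rep$perClass$recall[1], tp / (tp + fn))
    expect_equal(rep$accuracy, (cm[1, 1] + cm[2, 2]) / sum(cm))
  }

  # zero denominator is undefined, not zero
  cm0 <- matrix(c(0, 5, 0, 5), 2, byrow = TRUE,
                dimnames = list(c("pos", "neg"), c("pos", "neg")))
  expect_warning(rep0 <- computeMetrics(cm0), "denominator")
  expect_true(is.na(rep0$perClass$precision[1]))

  expect_error(computeMetrics(matrix(1, 3, 3)), "2x2")
})

test_that("stratified folds preserve counts and separate perfectly separable data", {
  set.seed(55)
  y <- rep(c("co-deleted", "non-deleted"), c(102, 57))
  d <- data.frame(f1 = ifelse(y == "co-deleted", 5, -5) + rnorm(159, sd = 0.1))
  rep <- stratifiedKFoldCV(d, y, k = 10, iterations = 10, seed = 55)
  expect_equal(rep$accuracy, 1.0)
  expect_equal(sum(rep$confusion), 159)
  foldSizes <- table(rep$predictions$fold)
  expect_true(all(foldSizes %in% c(15, 16)))
  expect_equal(rep$auc, 1.0)

  expect_error(stratifiedKFoldCV(d, y, k = 70), "reduce k")
})

test_that("rank AUC matches the Mann-Whitney construction", {
  score <- c(0.9, 0.8, 0.4, 0.3, 0.2)
  labels <- c("p", "p", "n", "p", "n")
  # pairs: (0.9,0.4)+, (0.9,0.2)+, (0.8,0.4)+, (0.8,0.2)+, (0.3,0.4)-, (0.3,0.2)+
  expect_equal(rankAUC(score, labels, "p"), 5 / 6)
  expect_true(is.na(rankAUC(score, rep("p", 5), "p")))
})
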