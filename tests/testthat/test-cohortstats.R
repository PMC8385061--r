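test_that("sign classification with ties going to control", {
  recs <- data.frame(nai_mean = c(0.4, -0.2, 0, 0.001))
  expect_equal(classifyBySign(recs, "nai"),
               c("cancer", "control", "control", "cancer"))
  expect_error(classifyBySign(data.frame(x = 1), "nai"), "missing")
})

test_that("confusion metrics match the published confusion arithmetic", {
  truth <- rep(c("cancer", "control"), each = 36)
  pred <- c(rep("cancer", 27), rep("control", 9),
            rep("control", 35), "cancer")
  cm <- confusionMetrics(truth, pred)
  expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$specificity, 35 / 36)
  expect_equal(cm$accuracy, 62 / 72)

  perfect <- confusionMetrics(truth, truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  flipped <- confusionMetrics(truth, rev(truth))
  expect_equal(flipped$accuracy, 0)
  expect_error(confusionMetrics(c("a", "b", "c"), c("a", "b", "c")), "two")
})

test_that("confusion metrics are permutation-equivariant and calibrate to 0.5 on random labels", {
  truth <- rep(c("cancer", "control"), each = 10)
  set.seed(8)
  pred <- sample(truth)
  perm <- sample(20)
  cm1 <- confusionMetrics(truth, pred)
  cm2 <- confusionMetrics(truth[perm], pred[perm])
  expect_equal(cm1, cm2)

  nRep <- 1000
  acc <- vapply(seq_len(nRep), function(i)
    confusionMetrics(truth, sample(truth))$accuracy, numeric(1))
  se <- sd(acc) / sqrt(nRep)
  expect_lt(abs(mean(acc) - 0.5), 3 * se)
})

test_that("ROC endpoints, tie handling, and the Mann-Whitney identity", {
  lab <- c("cancer", "cancer", "control", "control")
  expect_equal(rocCurve(c(3, 2, 1, 0), lab)$auc, 1)
  expect_equal(rocCurve(c(1, 1, 1, 1), lab)$auc, 0.5)
  expect_error(rocCurve(1:3, rep("cancer", 3)), "each class")

  # independent rank-statistic oracle: U / (n1 n2) with ties at 1/2
  uStat <- function(scores, lab) {
    pos <- scores[lab == "cancer"]; neg <- scores[lab != "cancer"]
    s <- 0
    for (p in pos) for (q in neg)
      s <- s + (p > q) + 0.5 * (p == q)
    s / (length(pos) * length(neg))
  }
  set.seed(42)
  for (r in 1:20) {
    lab <- sample(rep(c("cancer", "control"), times = c(7, 9)))
    scores <- sample(seq(-1, 1, 0.25), 16, replace = TRUE)  # forces ties
    expect_equal(rocCurve(scores, lab)$auc, uStat(scores, lab))
  }
})

test_that("AUC agrees with pROC and is invariant under monotone transforms", {
  set.seed(9)
  lab <- rep(c("cancer", "control"), each = 15)
  scores <- c(rnorm(15, 0.5), rnorm(15, -0.2))
  mine <- rocCurve(scores, lab)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = lab, predictor = scores, levels = c("control", "cancer"),
    direction = "<", quiet = TRUE)))
  expect_equal(mine, ref)
  expect_equal(rocCurve(exp(3 * scores), lab)$auc, mine)
  expect_equal(rocCurve(rank(scores), lab)$auc, mine)
})

test_that("two-variable PCA: degenerate geometries and algebraic identities", {
  # perfectly correlated indices put all variance on PC1
  x <- c(-0.5, 0, 0.25, 0.6)
  p <- pcaTwoVars(x, x)
  expect_equal(p$varianceFraction[1], 1)
  # uncorrelated, equal-variance variables split the variance evenly
  ci <- c(1, -1, 0, 0); nai <- c(0, 0, 1, -1)
  p2 <- pcaTwoVars(ci, nai)
  expect_equal(p2$varianceFraction, c(0.5, 0.5))
  # identities on arbitrary data: fractions sum to 1, exact reconstruction
  set.seed(3)
  m <- cbind(runif(12, -1, 1), runif(12, -1, 1))
  p3 <- pcaTwoVars(m)
  expect_equal(sum(p3$varianceFraction), 1)
  rec <- p3$scores %*% t(p3$loadings)
  rec <- sweep(rec, 2, p3$center, "+")
  expect_equal(unname(rec), unname(m))
  expect_error(pcaTwoVars(rep(0.2, 5), rep(-0.1, 5)), "degenerate")
  expect_error(pcaTwoVars(1:2, 1:2), "at least 3")
})

test_that("PC1 is oriented so the cancer group scores positive", {
  set.seed(14)
  g <- rep(c("cancer", "control"), each = 10)
  nai <- c(rnorm(10, 0.6, 0.1), rnorm(10, -0.6, 0.1))
  ci <- 0.5 * nai + rnorm(20, 0, 0.05)
  p <- pcaTwoVars(ci, nai, groups = g)
  expect_gt(mean(p$scores[g == "cancer", "PC1"]), 0)
  expect_gt(p$loadingFractionNai, 0.5)
})

test_that("accuracy and AUC are non-decreasing as group separation widens", {
  seps <- list(c(0.55, 0.45), c(0.7, 0.3), c(0.9, 0.1))
  set.seed(60)
  mAcc <- mAuc <- numeric(length(seps))
  for (k in seq_along(seps)) {
    accs <- aucs <- numeric(40)
    for (r in 1:40) {
      g <- generateCohort(nPerGroup = 12, pActCancer = seps[[k]][1],
                          pActControl = seps[[k]][2],
                          rngSeed = sample.int(1e6, 1))
      recs <- do.call(rbind, lapply(split(g$cohort, g$cohort$subject_id),
                                    aggregateSubject))
      cm <- confusionMetrics(recs$group, classifyBySign(recs, "nai"))
      accs[r] <- cm$accuracy
      aucs[r] <- rocCurve(recs$nai_mean, recs$group)$auc
    }
    mAcc[k] <- mean(accs); mAuc[k] <- mean(aucs)
  }
  tol <- 3 * 0.5 / sqrt(40)   # generous 3-SE band for 40 replicates
  expect_true(all(diff(mAcc) > -tol))
  expect_true(all(diff(mAuc) > -tol))
})

test_that("the discrimination report separates a well-separated synthetic cohort", {
  g <- generateCohort(nPerGroup = 12, pActCancer = 0.9, pActControl = 0.1,
                      rngSeed = 5)
  recs <- do.call(rbind, lapply(split(g$cohort, g$cohort$subject_id),
                                aggregateSubject))
  set.seed(6)
  recs$ci_mean <- rnorm(nrow(recs),
                        ifelse(recs$group == "cancer", 0.3, -0.3), 0.1)
  rep <- discriminate(recs)
  expect_gte(rep$accuracy, 0.9)
  expect_gte(rep$auc_nai, 0.95)
  expect_true(all(rep$predictions$predicted %in% c("cancer", "control")))
  expect_equal(sum(rep$pca$varianceFraction), 1)
})
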