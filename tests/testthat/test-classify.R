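# A linearly separable two-class feature table for classifier tests.
toyTable <- function(nHic, nNonHic, shift = 3, seed = 1, nNoise = 3) {
  set.seed(seed)
  n <- nHic + nNonHic
  lab <- c(rep("HIC", nHic), rep("non-HIC", nNonHic))
  x <- data.frame(signal = stats::rnorm(n) + ifelse(lab == "HIC", shift, 0))
  for (j in seq_len(nNoise)) x[[paste0("noise", j)]] <- stats::rnorm(n)
  cbind(label = factor(lab, levels = c("non-HIC", "HIC")), x)
}

test_that("training-set balancing subsamples the majority class", {
  tab <- toyTable(23, 200)
  bal <- balanceTrainingSet(tab, seed = 4)
  expect_equal(nrow(bal), 46)
  expect_equal(sum(bal$label == "HIC"), 23)
  expect_equal(sum(bal$label == "non-HIC"), 23)

  small <- toyTable(5, 5)
  balS <- balanceTrainingSet(small, seed = 1)
  expect_setequal(rownames(balS), rownames(small))

  expect_identical(balanceTrainingSet(tab, seed = 9),
                   balanceTrainingSet(tab, seed = 9))
  expect_warning(balanceTrainingSet(tab, nPerClass = 40, seed = 1),
                 "using all")
  expect_error(balanceTrainingSet(tab[tab$label == "HIC", ], seed = 1),
               "each class")
})

test_that("elastic net selects the informative feature and survives separation", {
  tab <- toyTable(25, 25, shift = 4, seed = 2)
  fit <- fitHicModel(tab[, -1], tab$label, seed = 1)
  expect_s4_class(fit, "HicModel")
  expect_true(fit@coefficients["signal"] > 0)
  expect_lt(max(abs(fit@coefficients[paste0("noise", 1:3)])),
            abs(fit@coefficients["signal"]))
  p <- predict(fit, tab[, -1], type = "response")
  expect_true(all(p > 0 & p < 1))
  expect_gte(aucScore(p, tab$label), 0.99)

  # constant features are harmless and get zero weight
  tab$flatline <- 1
  fit2 <- fitHicModel(tab[, -1], tab$label, seed = 1)
  expect_equal(unname(fit2@coefficients["flatline"]), 0)
})

test_that("labels independent of the features give chance-level models", {
  set.seed(6)
  aucs <- replicate(5, {
    tab <- toyTable(20, 20, shift = 0, seed = sample.int(1e6, 1))
    fit <- fitHicModel(tab[, -1], tab$label, seed = 1)
    tabTest <- toyTable(20, 20, shift = 0, seed = sample.int(1e6, 1))
    aucScore(predict(fit, tabTest[, -1]), tabTest$label)
  })
  expect_gt(median(aucs), 0.3)
  expect_lt(median(aucs), 0.7)
})

test_that("Youden threshold maximises J over all cut-points", {
  sep <- youdenThreshold(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(sep$threshold, 0.5)
  expect_equal(sep$J, 1)

  # exhaustive oracle on random scores
  set.seed(11)
  for (rep in 1:5) {
    p <- stats::runif(60)
    y <- stats::runif(60) < 0.3
    if (!any(y) || all(y)) next
    got <- youdenThreshold(p, y)
    u <- sort(unique(p))
    cand <- (u[-1] + u[-length(u)]) / 2
    Jall <- sapply(cand, function(th)
      mean(p[y] > th) + mean(p[!y] <= th) - 1)
    expect_equal(got$J, max(Jall))
    expect_equal(got$threshold, cand[which(Jall == max(Jall))[1]])
  }

  degen <- youdenThreshold(rep(0.4, 10), c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_true(degen$degenerate)
  expect_equal(degen$J, 0)
  expect_error(youdenThreshold(runif(5), rep(TRUE, 5)), "both classes")
})

test_that("evaluation reports perfect metrics for an oracle classifier", {
  # feature equals the label indicator: probabilities reproduce the labels
  tab <- data.frame(label = factor(c(rep("HIC", 20), rep("non-HIC", 200)),
                                   levels = c("non-HIC", "HIC")))
  tab$signal <- as.numeric(tab$label == "HIC")
  model <- new("HicModel", coefficients = c(signal = 10), intercept = -5,
               mixingAlpha = 0.5, shrinkageLambda = 0.1,
               probabilityThreshold = 0.5,
               trainingMetadata = list())
  rep <- evaluateModel(model, tab, nIterations = 10, seed = 5)
  expect_equal(unname(rep@medians[c("auc", "balancedAccuracy", "kappa")]),
               c(1, 1, 1))
  expect_true(all(rep@iterations$sensitivity == 1))
  expect_error(evaluateModel(model, tab[1:20, ], nIterations = 2, seed = 1),
               "too small")
})

test_that("evaluation subsampling is seeded and respects the 1:10 design", {
  tab <- toyTable(20, 200, shift = 2, seed = 8)
  fit <- fitHicModel(tab[, -1], tab$label, seed = 2)
  a <- evaluateModel(fit, tab, nIterations = 7, seed = 31)
  b <- evaluateModel(fit, tab, nIterations = 7, seed = 31)
  expect_identical(a@iterations, b@iterations)
  expect_equal(a@nIterations, 7L)
  # sensitivity quantised to fifths, specificity to fiftieths
  expect_true(all(abs(a@iterations$sensitivity * 5 -
                        round(a@iterations$sensitivity * 5)) < 1e-12))
  expect_true(all(abs(a@iterations$specificity * 50 -
                        round(a@iterations$specificity * 50)) < 1e-12))
})

test_that("AUC is rank-based and invariant to monotone transforms", {
  set.seed(13)
  p <- stats::runif(80)
  y <- stats::runif(80) < 0.4
  a <- aucScore(p, y)
  expect_equal(aucScore(stats::qlogis(p), y), a, tolerance = 1e-12)
  expect_equal(aucScore(p^3, y), a, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                                 direction = "<",
                                                 levels = c(FALSE, TRUE)))),
               tolerance = 1e-12)
})

test_that("Cohen's kappa matches direct contingency arithmetic", {
  expect_equal(cohensKappa(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE)), 1)

  # TP=5, FN=0, FP=7, TN=43
  pred <- c(rep(TRUE, 5), rep(TRUE, 7), rep(FALSE, 43))
  truth <- c(rep(TRUE, 5), rep(FALSE, 7), rep(FALSE, 43))
  po <- (5 + 43) / 55
  pe <- (12 / 55) * (5 / 55) + (43 / 55) * (50 / 55)
  expect_equal(cohensKappa(pred, truth), (po - pe) / (1 - pe),
               tolerance = 1e-12)

  set.seed(17)
  big <- cohensKappa(stats::runif(1e4) < 0.5, stats::runif(1e4) < 0.5)
  expect_lt(abs(big), 0.05)

  expect_equal(cohensKappa(rep(TRUE, 4), rep(TRUE, 4)), 1)
})

test_that("odds ratios are the exponentiated coefficients", {
  model <- new("HicModel",
               coefficients = c(a = 0, b = log(2), c = -2.66), intercept = 0,
               mixingAlpha = 0.5, shrinkageLambda = 1,
               probabilityThreshold = 0.5, trainingMetadata = list())
  or <- oddsRatios(model)
  expect_identical(unname(or["a"]), 1)
  expect_equal(unname(or["b"]), 2, tolerance = 1e-12)
  expect_equal(unname(or["c"]), exp(-2.66), tolerance = 1e-12)
})

test_that("model serialisation round-trips through plain text", {
  tab <- toyTable(15, 60, seed = 4)
  fit <- fitHicModel(tab[, -1], tab$label, seed = 3)
  path <- withr::local_tempfile(fileext = ".txt")
  writeHicModel(fit, path)
  back <- readHicModel(path)
  expect_equal(back@coefficients, fit@coefficients)
  expect_equal(back@intercept, fit@intercept)
  expect_equal(back@probabilityThreshold, fit@probabilityThreshold)
  expect_equal(predict(back, tab[, -1]), predict(fit, tab[, -1]))
})
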