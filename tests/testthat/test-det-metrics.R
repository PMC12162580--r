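# Detection evaluation: box IoU, greedy matching, P/R/F1, PR/AP, mAP, ROC
# AUC and the paired comparison, against closed-form and brute-force
# oracles.

test_that("box IoU handles identity, disjointness and the half-overlap case", {
  b <- c(0.4, 0.4, 0.2, 0.3)
  expect_equal(boxIou(b, b), 1)
  expect_equal(boxIou(c(0.2, 0.2, 0.1, 0.1), c(0.8, 0.8, 0.1, 0.1)), 0)
  # unit-square halves sharing a half-width overlap
  expect_equal(boxIou(c(0.25, 0.5, 0.5, 1), c(0.5, 0.5, 0.5, 1)), 1 / 3)
})

test_that("matching: exact hit, duplicate suppression, one-to-one rule", {
  t1 <- data.frame(category = "Fracture(R)", cx = 0.3, cy = 0.3, w = 0.2, h = 0.2)
  d1 <- cbind(t1, confidence = 0.9)
  mm <- matchDetections(d1, t1)
  expect_equal(unname(mm$confusion), c(1, 0, 0))
  d2 <- rbind(d1, cbind(t1, confidence = 0.7))  # second det on same truth
  mm2 <- matchDetections(d2, t1)
  expect_equal(unname(mm2$confusion), c(1, 1, 0))
  expect_true(mm2$detTp[1])                     # higher confidence wins
  expect_false(mm2$detTp[2])
})

test_that("greedy matching equals the brute-force matcher on random scenes", {
  set.seed(99)
  for (rep in 1:300) {
    dets <- randomBoxes(sample(0:5, 1), withConf = TRUE)
    truths <- randomBoxes(sample(1:4, 1))
    mm <- matchDetections(dets, truths, 0.5)
    expect_identical(unname(mm$confusion), unname(oracleMatch(dets, truths, 0.5)))
  }
})

test_that("precision/recall/F1 follow the count formulas with 0/0 -> 0", {
  cf <- c(tp = 6, fp = 2, fn = 3)
  expect_equal(detPrecision(cf), 6 / 8)
  expect_equal(detRecall(cf), 6 / 9)
  expect_equal(detF1(cf), 12 / (12 + 2 + 3))
  expect_equal(detF1(c(tp = 0, fp = 0, fn = 0)), 0)
  expect_equal(detPrecision(c(tp = 0, fp = 0, fn = 4)), 0)
})

test_that("F1 from counts equals the harmonic mean of precision and recall", {
  set.seed(4)
  for (rep in 1:50) {
    cf <- c(tp = sample(0:20, 1), fp = sample(0:20, 1), fn = sample(0:20, 1))
    p <- detPrecision(cf); r <- detRecall(cf)
    if (p + r > 0) expect_equal(detF1(cf), 2 * p * r / (p + r))
  }
  expect_equal(f1Score(1, 1), 1)
})

test_that("AP of hand-enumerated sweeps matches the interpolated area", {
  tr <- data.frame(category = rep("Fracture(R)", 2),
                   cx = c(0.25, 0.75), cy = 0.5, w = 0.2, h = 0.2)
  dets <- data.frame(category = "Fracture(R)",
                     cx = c(0.25, 0.25, 0.75, 0.75), cy = c(0.5, 0.9, 0.5, 0.1),
                     w = 0.2, h = 0.2,
                     confidence = c(0.9, 0.8, 0.7, 0.6))
  # sweep: TP, FP, TP, FP -> envelope area = 0.5*1 + 0.5*(2/3)
  cur <- prCurve(dets, tr)
  expect_equal(cur$recall, c(0.5, 0.5, 1, 1))
  expect_equal(cur$precision, c(1, 1 / 2, 2 / 3, 1 / 2))
  expect_equal(averagePrecision(cur), 5 / 6)
})

test_that("single-TP and all-FP sweeps give AP 1 and 0, and no truths errors", {
  tr <- data.frame(category = "Fracture(L)", cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  hit <- cbind(tr, confidence = 0.8)
  expect_equal(averagePrecision(prCurve(hit, tr)), 1)
  miss <- data.frame(category = "Fracture(L)", cx = 0.1, cy = 0.1, w = 0.05,
                     h = 0.05, confidence = 0.8)
  expect_equal(averagePrecision(prCurve(miss, tr)), 0)
  expect_error(prCurve(hit, tr[0, ]), "at least one ground-truth")
})

test_that("AP moves the right way when detections are appended", {
  set.seed(21)
  for (rep in 1:20) {
    truths <- randomBoxes(3)
    dets <- randomBoxes(4, withConf = TRUE)
    ap0 <- averagePrecision(prCurve(dets, truths))
    lowFp <- rbind(dets, data.frame(category = truths$category[1],
                                    cx = 0.95, cy = 0.95, w = 0.02, h = 0.02,
                                    confidence = min(dets$confidence) / 2))
    expect_lte(averagePrecision(prCurve(lowFp, truths)), ap0 + 1e-12)
    highTp <- rbind(data.frame(truths[1, ],
                               confidence = max(dets$confidence) + 0.05),
                    dets)
    expect_gte(averagePrecision(prCurve(highTp, truths)), ap0 - 1e-12)
  }
})

test_that("mAP is the arithmetic mean of per-category AP", {
  expect_equal(meanAp(c(a = 0.5, b = 0.7)), 0.6)
  expect_equal(meanAp(list(0.83)), 0.83)
  set.seed(2)
  v <- runif(7)
  expect_equal(meanAp(v), sum(v) / length(v))
  expect_error(meanAp(numeric()), "empty")
})

test_that("ROC AUC equals all-pairs concordance and handles separation/ties", {
  expect_equal(rocAuc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(rocAuc(rep(5, 8), rep(0:1, 4)), 0.5)
  set.seed(8)
  for (rep in 1:20) {
    sc <- sample(1:5, 12, TRUE)       # ties likely
    lb <- c(rep(0, 6), rep(1, 6))[sample(12)]
    expect_equal(rocAuc(sc, lb), oracleAuc(sc, lb))
  }
  expect_error(rocAuc(1:4, rep(1, 4)), "both label values")
})

test_that("ROC AUC is invariant under strictly monotone score transforms", {
  set.seed(13)
  sc <- rnorm(30)
  lb <- rbinom(30, 1, 0.5)
  lb[1] <- 0; lb[2] <- 1
  a <- rocAuc(sc, lb)
  expect_equal(rocAuc(exp(sc), lb), a)
  expect_equal(rocAuc(2 * sc + 7, lb), a)
})

test_that("ROC AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  sc <- round(rnorm(40), 1)
  lb <- rbinom(40, 1, 0.4)
  lb[1] <- 0; lb[2] <- 1
  expect_equal(rocAuc(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<"))))
})

test_that("paired t test: sign convention, degeneracy, textbook formula", {
  before <- c(0.60, 0.55, 0.62, 0.58, 0.61)
  res <- pairedTTest(before, before + 0.2 + rnorm(5, sd = 1e-4))
  expect_lt(res$t, 0)                       # improvement -> negative t
  expect_lt(res$p, 0.05)
  deg <- pairedTTest(before, before)
  expect_true(deg$degenerate)
  a <- c(5.1, 4.8, 6.0, 5.5, 5.2)
  b <- c(4.9, 4.9, 5.1, 5.0, 4.8)
  d <- a - b
  tHand <- mean(d) / (sd(d) / sqrt(5))
  res2 <- pairedTTest(a, b)
  expect_equal(res2$t, tHand)
  expect_equal(res2$df, 4)
  expect_equal(res2$p, 2 * pt(-abs(tHand), 4))
  expect_error(pairedTTest(1:3, 1:4), "length mismatch")
})

test_that("per-side diagnosis follows the highest-confidence rule", {
  d <- data.frame(category = "Fracture(L)", cx = 0.7, cy = 0.4, w = 0.2,
                  h = 0.2, confidence = 0.9)
  call <- diagnosisFromDetections(d)
  expect_true(call[["L"]])
  expect_false(call[["R"]])
  d2 <- data.frame(category = c("Fracture(R)", "Non-fracture(R)"),
                   cx = 0.3, cy = 0.4, w = 0.2, h = 0.2,
                   confidence = c(0.6, 0.8))
  expect_false(diagnosisFromDetections(d2)[["R"]])   # higher confidence wins
  d2$confidence <- c(0.8, 0.6)
  expect_true(diagnosisFromDetections(d2)[["R"]])
})

test_that("diagnosis rule equals its brute-force application on random sets", {
  set.seed(31)
  for (rep in 1:50) {
    d <- randomBoxes(sample(0:6, 1), withConf = TRUE)
    call <- diagnosisFromDetections(d)
    for (side in c("R", "L")) {
      sel <- d[grepl(paste0("\\(", side, "\\)"), d$category), ]
      want <- if (nrow(sel) == 0) FALSE else
        grepl("^Fracture", sel$category[which.max(sel$confidence)])
      expect_identical(unname(call[[side]]), want)
    }
  }
})
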