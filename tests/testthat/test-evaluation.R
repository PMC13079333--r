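test_that("frame accuracy is a Kronecker-delta average", {
  expect_equal(frame_accuracy(c("a", "b"), c("a", "b")), 100)
  expect_equal(frame_accuracy(c("a", "b"), c("b", "a")), 0)
  expect_equal(frame_accuracy(c("a", "a", "b", "b"), c("a", "a", "b", "a")), 75)
  expect_error(frame_accuracy("a", c("a", "b")), "length")
  expect_error(frame_accuracy(character(), character()), "empty")
})

test_that("class metrics match a hand-tabulated confusion", {
  truth <- c("A", "A", "B", "B")
  pred <- c("A", "B", "B", "B")
  m <- class_metrics(pred, truth)
  b <- m[m$class == "B", ]
  expect_equal(b$precision, 2 / 3)
  expect_equal(b$recall, 1)
  expect_equal(b$f1, 0.8)
  # perfect prediction
  p <- class_metrics(truth, truth)
  expect_true(all(p$precision == 1) && all(p$recall == 1) && all(p$f1 == 1))
  # class never predicted: recall 0; class absent from both: NA
  m2 <- class_metrics(c("A", "A"), c("A", "B"), classes = c("A", "B", "C"))
  expect_equal(m2$recall[m2$class == "B"], 0)
  expect_true(is.na(m2$f1[m2$class == "C"]))
})

test_that("timing errors reflect pure shifts and count misses", {
  fs <- 100
  truth <- rep(c("Sitting", "SiTSt", "Standing"), times = c(100, 50, 100))
  expect_equal(transition_timing_error(truth, truth, fs)$error_ms, 0)
  pred <- c(rep("Sitting", 105), rep("SiTSt", 50), rep("Standing", 95))
  tt <- transition_timing_error(pred, truth, fs)
  expect_equal(tt$error_ms, 50)  # +5 frames at 100 Hz
  # a missing transition becomes a miss; others are unaffected
  pred2 <- rep("Sitting", 250)
  tt2 <- transition_timing_error(pred2, truth, fs)
  expect_equal(attr(tt2, "misses"), 1)
  expect_true(all(is.na(tt2$error_ms)))
})

test_that("false detection rate reproduces printed worked examples", {
  # 3 of 1361 Sitting frames predicted as the following transition
  truth <- rep("Sitting", 1361)
  pred <- c(rep("SiTSt", 3), rep("Sitting", 1358))
  expect_equal(round(false_detection_rate(pred, truth, "Sitting", "SiTSt"), 2),
               0.22)
  # 105 of 2386 Standing frames predicted as stand-to-sit
  truth2 <- rep("Standing", 2386)
  pred2 <- c(rep("StTSi", 105), rep("Standing", 2281))
  expect_equal(round(false_detection_rate(pred2, truth2, "Standing", "StTSi"), 2),
               4.40)
  expect_equal(false_detection_rate(truth, truth, "Sitting", "SiTSt"), 0)
  expect_error(false_detection_rate(pred, truth, "Standing", "StTSi"),
               "no frames")
})

test_that("confusion matrix rows are percentages summing to 100", {
  truth <- c("A", "A", "B", "B", "B", "C")
  pred <- c("A", "B", "B", "B", "A", "C")
  cm <- confusion_matrix_norm(pred, truth)
  expect_equal(unname(rowSums(cm$percent)), rep(100, 3))
  expect_equal(cm$counts["B", "A"], 1)
  # identity for perfect prediction
  cmp <- confusion_matrix_norm(truth, truth)
  expect_equal(unname(cmp$percent), diag(3) * 100)
  # empty truth rows are NA
  cm2 <- confusion_matrix_norm(c("A", "A"), c("A", "A"),
                               classes = c("A", "B"))
  expect_true(all(is.na(cm2$percent["B", ])))
})

test_that("uniform random predictions fill the confusion matrix uniformly", {
  set.seed(8)
  classes <- c("w", "x", "y", "z")
  truth <- sample(classes, 40000, replace = TRUE)
  pred <- sample(classes, 40000, replace = TRUE)
  cm <- confusion_matrix_norm(pred, truth, classes)
  expect_true(all(abs(cm$percent - 25) < 2.5))  # Monte-Carlo tolerance
})

test_that("averaging two row-normalized matrices is element-wise", {
  a <- confusion_matrix_norm(c("A", "B"), c("A", "B"), classes = c("A", "B"))
  b <- confusion_matrix_norm(c("B", "B"), c("A", "B"), classes = c("A", "B"))
  avg <- (a$percent + b$percent) / 2
  expect_equal(avg["A", "A"], 50)
  expect_equal(avg["B", "B"], 100)
})

test_that("report-internal consistency: accuracy, confusion and micro recall", {
  set.seed(9)
  classes <- sts_states("four")
  truth <- sample(classes, 3000, replace = TRUE, prob = c(4, 1, 4, 1))
  pred <- ifelse(runif(3000) < 0.8, truth, sample(classes, 3000, TRUE))
  ev <- evaluate_predictions(pred, truth, fs = 100, classes = classes)
  # accuracy equals the trace mass of the unnormalized confusion matrix
  expect_equal(ev$accuracy_percent,
               100 * sum(diag(ev$confusion$counts)) / ev$n)
  # micro-averaged recall equals accuracy in the unweighted case
  micro <- sum(ev$metrics$recall * ev$metrics$n_truth) / sum(ev$metrics$n_truth)
  expect_equal(100 * micro, ev$accuracy_percent)
  # FDR agrees with the corresponding confusion cell
  fdr <- false_detection_rate(pred, truth, "Sitting", "SiTSt")
  expect_equal(fdr, ev$confusion$percent["Sitting", "SiTSt"])
})
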