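test_that("confusion3 counts predictions against expert labels", {
  cm <- confusion3(
    y_true = c("Present", "Unknown", "Absent"),
    y_pred = c("Present", "Unknown", "Absent")
  )
  expect_equal(diag(unclass(cm)), setNames(rep(1L, 3), MURMUR_CLASSES))
  expect_equal(sum(cm), 3)

  cm <- confusion3(
    y_true = c("Present", "Present", "Unknown"),
    y_pred = rep("Absent", 3)
  )
  expect_equal(unclass(cm)["Absent", "Present"], 2L)
  expect_equal(unclass(cm)["Absent", "Unknown"], 1L)
  expect_equal(sum(cm), 3)

  expect_error(confusion3("Maybe", "Present"), "invalid murmur label")
  expect_error(confusion3(c("Present", "Absent"), "Present"), "equal length")
})

test_that("weighted accuracy reproduces the worked oracle values", {
  cls <- MURMUR_CLASSES
  cm <- matrix(0, 3, 3, dimnames = list(cls, cls))
  cm["Present", "Present"] <- 8
  cm["Absent", "Present"] <- 2
  cm["Unknown", "Unknown"] <- 3
  cm["Present", "Unknown"] <- 1
  cm["Absent", "Absent"] <- 15
  cm["Present", "Absent"] <- 5
  expect_equal(weighted_accuracy(cm), 64 / 82)

  cm2 <- matrix(0, 3, 3, dimnames = list(cls, cls))
  cm2["Absent", "Present"] <- 10
  cm2["Unknown", "Unknown"] <- 2
  cm2["Absent", "Absent"] <- 5
  expect_equal(weighted_accuracy(cm2), 11 / 61)

  # perfect diagonal scores 1 regardless of the counts
  expect_equal(weighted_accuracy(diag(c(7, 2, 31))), 1)
  expect_error(weighted_accuracy(matrix(0, 3, 3)), "undefined")
})

test_that("weighted accuracy is bounded and generalizes plain accuracy", {
  set.seed(1)
  for (i in 1:200) {
    cm <- matrix(rpois(9, 5), 3, 3)
    if (sum(cm) == 0) next
    w <- weighted_accuracy(cm)
    expect_gte(w, 0)
    expect_lte(w, 1)
    expect_equal(weighted_accuracy(cm, weights = c(1, 1, 1)),
                 sum(diag(cm)) / sum(cm))
  }
})

test_that("outcome cost matches the literal expression on random tuples", {
  expect_equal(outcome_cost(list(N = 100, M = 10, TP = 5, FN = 5)),
               3058.6496)
  expect_equal(outcome_cost(list(N = 10, M = 0, TP = 0, FN = 0)), 35)

  set.seed(2)
  for (i in 1:1000) {
    N <- sample(1:500, 1)
    M <- sample(0:N, 1)
    TP <- sample(0:M, 1)
    FN <- sample(0:(N - M), 1)
    got <- outcome_cost(list(N = N, M = M, TP = TP, FN = FN))
    want <- literal_cost(N, M, TP, FN)
    expect_lt(abs(got - want) / max(1, abs(want)), 1e-9)
  }
})

test_that("each missed abnormal patient costs exactly 50000/N more", {
  base <- outcome_cost(list(N = 50, M = 10, TP = 8, FN = 3))
  more <- outcome_cost(list(N = 50, M = 10, TP = 8, FN = 4))
  expect_equal(more - base, 50000 / 50)
  expect_error(outcome_cost(list(N = 10, M = 11, TP = 0, FN = 0)), "invalid")
  expect_error(outcome_cost(list(N = 0, M = 0, TP = 0, FN = 0)), "N < 1")
})

test_that("outcome counts are assembled from labels", {
  y_true <- c("Abnormal", "Abnormal", "Normal", "Normal", "Abnormal")
  y_pred <- c("Abnormal", "Normal", "Abnormal", "Normal", "Abnormal")
  oc <- outcome_counts(y_true, y_pred)
  expect_equal(oc$N, 5)
  expect_equal(oc$M, 3)
  expect_equal(oc$TP, 2)
  expect_equal(oc$FN, 1)
})

test_that("rank-based AUC equals brute-force pairwise counting", {
  expect_equal(pcgst:::auc_rank(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)), 0.75)
  set.seed(3)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5)) # both classes present
    scores <- round(runif(n), 2)             # ties likely
    expect_equal(pcgst:::auc_rank(labels, scores), brute_auc(labels, scores))
  }
})

test_that("rank-based AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  labels <- rbinom(80, 1, 0.4)
  scores <- rnorm(80) + labels
  got <- pcgst:::auc_rank(labels, scores)
  want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("binary metrics handle perfect, reversed and degenerate input", {
  m <- binary_metrics(c("p", "p", "n", "n"), c("p", "p", "n", "n"),
                      scores = c(0.9, 0.8, 0.2, 0.1), positive = "p")
  expect_equal(unlist(m), c(acc = 1, se = 1, sp = 1, f_score = 1, auc = 1))

  m <- binary_metrics(c("p", "p", "n", "n"), c("p", "p", "n", "n"),
                      scores = c(0.1, 0.2, 0.8, 0.9), positive = "p")
  expect_equal(m$auc, 0)

  # no positive patients: SE and precision are both undefined
  expect_warning(
    expect_warning(
      m <- binary_metrics(c("n", "n"), c("n", "n"), positive = "p"),
      "sensitivity undefined"
    ),
    "precision undefined"
  )
  expect_true(is.nan(m$se))
  expect_error(pcgst:::auc_rank(c(1, 1), c(0.5, 0.2)), "both classes")
})

test_that("macro averaging is the unweighted class mean", {
  expect_equal(macro_average(c(0.4, 0.4, 0.4)), 0.4)
  expect_equal(macro_average(c(1, 0.5)), 0.75)
  expect_equal(macro_average(c(0.2, 0.9, 0.7)),
               macro_average(c(0.9, 0.7, 0.2)))
  expect_error(macro_average(numeric(0)), "at least one")
})

test_that("binary weighted accuracy weights abnormal detections 5x", {
  y_true <- c("Abnormal", "Abnormal", "Normal", "Normal")
  expect_equal(weighted_accuracy_binary(y_true, y_true), 1)
  # one missed abnormal out of two, normals perfect: (5 + 2) / (10 + 2)
  expect_equal(
    weighted_accuracy_binary(y_true, c("Abnormal", "Normal", "Normal", "Normal")),
    7 / 12
  )
})
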