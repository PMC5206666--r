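test_that("ROC curves have the right endpoints and pass through (0,1) for separable scores", {
  df <- tibble::tibble(s = c(0.9, 0.8, 0.3, 0.2), y = c(TRUE, TRUE, FALSE, FALSE))
  roc <- roc_curve(df, s, y)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  expect_equal(roc_auc(roc), 1)
  expect_error(roc_curve(tibble::tibble(s = 1:3, y = c(TRUE, TRUE, TRUE)), s, y),
    class = "holocyte_single_class"
  )
})

test_that("ROC matches the brute-force confusion-matrix oracle on random instances", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(10:200, 1)
    scores <- round(rnorm(n), sample(0:2, 1)) # ties included
    truth <- runif(n) < 0.4
    if (length(unique(truth)) < 2) next
    got <- roc_curve(tibble::tibble(s = scores, y = truth), s, y)
    want <- roc_bruteforce(scores, truth)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$fpr, want$fpr)
    expect_equal(got$tpr, want$tpr)
  }
})

test_that("random scores give chance-level AUC", {
  set.seed(9)
  n <- 4000
  df <- tibble::tibble(s = rnorm(n), y = runif(n) < 0.5)
  expect_lt(abs(roc_auc(roc_curve(df, s, y)) - 0.5), 0.03)
})

test_that("sensitivity and specificity follow the confusion-matrix definitions", {
  all_right <- tibble::tibble(p = c(TRUE, TRUE, FALSE), y = c(TRUE, TRUE, FALSE))
  ss <- sensitivity_specificity(all_right, p, y)
  expect_equal(ss$sensitivity, 1)
  expect_equal(ss$specificity, 1)
  # 15 TP, 0 FN -> sensitivity 1 regardless of the negatives
  df <- tibble::tibble(
    p = c(rep(TRUE, 15), rep(TRUE, 5), rep(FALSE, 30)),
    y = c(rep(TRUE, 15), rep(FALSE, 35))
  )
  expect_equal(sensitivity_specificity(df, p, y)$sensitivity, 1)
  # known confusion matrix: TP=6, FN=0, FP=17, TN=93
  df2 <- tibble::tibble(
    p = c(rep(TRUE, 6), rep(TRUE, 17), rep(FALSE, 93)),
    y = c(rep(TRUE, 6), rep(FALSE, 110))
  )
  ss2 <- sensitivity_specificity(df2, p, y)
  expect_equal(ss2$sensitivity, 1)
  expect_equal(ss2$specificity, 93 / 110, tolerance = 1e-12)
})

test_that("inter-operator statistics reproduce the printed study arithmetic", {
  tab <- synthetic_operator_counts()
  expect_equal(nrow(tab), 72)
  st <- interoperator_stats(tab, cutoff = 10, quorum = 3)
  expect_equal(st$n_consensus_positive, 28)
  expect_equal(st$n_consensus_negative, 44)
  expect_equal(st$n_discordant, 12)
  expect_equal(st$rate_overall_pct, 16.7)
  expect_equal(st$rate_negative_pct, 20.5)
  expect_equal(st$rate_positive_pct, 10.7)
})

test_that("inter-operator statistics are invariant to row and column order", {
  tab <- synthetic_operator_counts()
  set.seed(3)
  shuffled <- tab[sample(nrow(tab)), c("specimen", sample(paste0("op", 1:5)))]
  st1 <- interoperator_stats(tab)
  st2 <- interoperator_stats(shuffled)
  expect_equal(st1$rate_overall_pct, st2$rate_overall_pct)
  expect_equal(st1$rate_negative_pct, st2$rate_negative_pct)
  expect_equal(st1$rate_positive_pct, st2$rate_positive_pct)
})

test_that("unanimous operators give zero discordance and ambiguous quorums error", {
  tab <- tibble::tibble(op1 = c(50, 2), op2 = c(50, 2), op3 = c(50, 2))
  st <- interoperator_stats(tab, quorum = 2)
  expect_equal(st$rate_overall_pct, 0)
  # 2-of-4 quorum lets both classes reach consensus: error
  amb <- tibble::tibble(op1 = 50, op2 = 50, op3 = 2, op4 = 2)
  expect_error(interoperator_stats(amb, quorum = 2), class = "holocyte_consensus_tie")
})

test_that("the shipped operator-count fixture matches the generator", {
  path <- system.file("extdata", "operator_counts_synthetic.csv", package = "holocyte")
  expect_true(nzchar(path))
  tab <- read_operator_counts(path)
  expect_equal(as.data.frame(tab), as.data.frame(synthetic_operator_counts()))
})

test_that("trapezoidal AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  scores <- rnorm(80)
  truth <- runif(80) < 0.5
  ours <- roc_auc(roc_curve(tibble::tibble(s = scores, y = truth), s, y))
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})
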