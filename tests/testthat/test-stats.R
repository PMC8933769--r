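test_that("chi-square matches the direct formula oracle on random tables", {
  chisq_oracle <- function(m) {
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - E)^2 / E)
  }
  set.seed(10)
  for (i in 1:25) {
    m <- matrix(rpois(4, lambda = 25) + 1, 2, 2)
    r <- chi_square_2x2(m)
    expect_equal(r$statistic, chisq_oracle(m), tolerance = 1e-12)
    expect_equal(r$p_value, stats::pchisq(r$statistic, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
    # invariances: row swap, column swap, scaling all cells by k
    expect_equal(chi_square_2x2(m[2:1, ])$statistic, r$statistic)
    expect_equal(chi_square_2x2(m[, 2:1])$statistic, r$statistic)
    expect_equal(chi_square_2x2(3 * m)$statistic, 3 * r$statistic,
                 tolerance = 1e-9)
  }
})

test_that("degenerate and invalid contingency tables are handled", {
  r <- chi_square_2x2(matrix(c(5, 0, 7, 0), 2, 2))
  expect_true(r$degenerate)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(chi_square_2x2(rbind(c(39, 15), c(39, 15)))$statistic, 0,
               tolerance = 1e-12)
  expect_error(chi_square_2x2(matrix(c(-1, 2, 3, 4), 2, 2)), "non-negative")
})

test_that("ROC matches the Mann-Whitney oracle with ties counted half", {
  mw_auc <- function(scores, lab) {
    sp <- scores[lab]; sn <- scores[!lab]
    cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  # 12-point toy set with ties
  sc <- c(0, 1, 1, 2, 3, 3, 4, 5, 5, 6, 7, 7)
  lb <- c(F, F, T, F, F, T, T, F, T, T, T, T)
  r <- roc_analysis(sc, lb)
  expect_equal(r$auc, mw_auc(sc, lb), tolerance = 1e-9)

  set.seed(12)
  for (i in 1:10) {
    sc <- round(rnorm(40), 1)
    lb <- runif(40) < 0.4
    if (!any(lb) || all(lb)) next
    r <- roc_analysis(sc, lb)
    expect_equal(r$auc, mw_auc(sc, lb), tolerance = 1e-9)
    # complement symmetry for tie-free scores
    sc2 <- rnorm(40)
    expect_equal(roc_analysis(sc2, lb)$auc + roc_analysis(-sc2, lb)$auc, 1,
                 tolerance = 1e-9)
  }
})

test_that("ROC agrees with pROC and reports the max-accuracy operating point", {
  set.seed(13)
  sc <- c(rnorm(60, 10, 6), rnorm(40, 25, 6))
  lb <- rep(c(FALSE, TRUE), c(60, 40))
  r <- roc_analysis(sc, lb)
  skip_if_not_installed("pROC")
  pr <- pROC::roc(response = lb, predictor = sc, quiet = TRUE,
                  direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-9)

  # the reported accuracy is attained and is the sweep maximum
  acc_at <- function(t) 100 * (sum(sc >= t & lb) + sum(sc < t & !lb)) / length(sc)
  expect_equal(r$accuracy, acc_at(r$cutoff), tolerance = 1e-9)
  expect_equal(r$accuracy, max(r$curve$accuracy) * 100, tolerance = 1e-9)

  expect_equal(roc_analysis(c(1, 2, 3, 11, 12, 13),
                            c(F, F, F, T, T, T))$auc, 1)
  expect_equal(roc_analysis(c(1, 2, 3, 11, 12, 13),
                            c(F, F, F, T, T, T))$accuracy, 100)
  expect_error(roc_analysis(1:5, rep(TRUE, 5)), "both classes")
})

test_that("max-accuracy ties resolve to the lowest cutoff and labels parse", {
  # two thresholds reach the same accuracy; the lower one must be reported
  sc <- c(1, 2, 3, 4)
  lb <- c(FALSE, TRUE, FALSE, TRUE)
  r <- roc_analysis(sc, lb)
  alt <- r$curve$threshold[r$curve$accuracy == max(r$curve$accuracy)]
  expect_equal(r$cutoff, min(alt))

  expect_equal(roc_analysis(sc, c("negative", "positive", "negative", "positive"))$auc,
               roc_analysis(sc, lb)$auc)
  expect_equal(roc_analysis(sc, c(0, 1, 0, 1))$auc, roc_analysis(sc, lb)$auc)
})

test_that("the recovered CL cutoff tracks a known positivity threshold", {
  # pooled cohort emulation: true regional positivity switches at theta;
  # observed CL carries measurement noise
  # the truth is thresholded on a noisy copy of the score, so calls near
  # theta can flip but the operating point should still land next to it
  theta <- 14.4
  set.seed(14)
  hits <- 0
  for (rep in 1:100) {
    cl <- runif(120, -10, 60)
    labels <- (cl + rnorm(120, sd = 1)) >= theta
    r <- roc_analysis(cl, labels)
    s <- sort(cl)
    spacing <- max(diff(s[s > theta - 5 & s < theta + 5]))
    hits <- hits + (abs(r$cutoff - theta) <= spacing)
  }
  expect_gte(hits, 90)
})
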