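test_that("auc matches pair enumeration, including ties and flips", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(c(1, 1, 2), c(0, 1, 1)), 0.75)
  # label flip antisymmetry
  set.seed(5)
  s <- sample(1:6, 12, replace = TRUE)
  l <- sample(0:1, 12, replace = TRUE, prob = c(0.5, 0.5))
  if (length(unique(l)) < 2) l[1:2] <- c(0, 1)
  expect_equal(auc(s, 1 - l), 1 - auc(s, l))
  # pair-enumeration oracle on random tied instances
  for (rep in 1:30) {
    n <- sample(4:15, 1)
    s <- sample(1:5, n, replace = TRUE)
    l <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(auc(s, l), auc_pairs(s, l), tolerance = 1e-14)
  }
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("rank AUC equals trapezoidal ROC area to machine precision", {
  set.seed(10)
  for (rep in 1:200) {
    n <- sample(5:40, 1)
    scores <- if (rep %% 2) rnorm(n) else sample(1:4, n, replace = TRUE)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, auc(scores, labels), tolerance = 1e-12)
    # sweep invariants
    expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
    expect_equal(c(r$tpr[1], r$fpr[1]), c(0, 0))
    expect_equal(c(r$tpr[length(r$tpr)], r$fpr[length(r$fpr)]), c(1, 1))
  }
})

test_that("auc is invariant under strictly monotone score transforms", {
  set.seed(11)
  s <- rnorm(30)
  l <- sample(0:1, 30, replace = TRUE)
  l[1:2] <- c(0, 1)
  a <- auc(s, l)
  expect_equal(auc(exp(s), l), a)
  expect_equal(auc(rank(s), l), a)
})

test_that("U / (n m) complements the AUC orientation exactly", {
  set.seed(12)
  kd <- rnorm(9, 1)
  fc <- rnorm(7)
  scores <- c(kd, fc)
  labels <- rep(c(1, 0), c(9, 7))
  # U counts KD-above-FC pairs, so U/(n m) equals the AUC itself
  U <- mann_whitney_u(kd, fc)$U
  expect_equal(U / (9 * 7), auc(scores, labels), tolerance = 1e-14)
})

test_that("contingency tables are exact at every threshold", {
  scores <- c(0.1, 0.4, 0.6, 0.9)
  labels <- c(0, 0, 1, 1)
  lo <- contingency_at_threshold(scores, labels, 0.05)
  expect_equal(c(lo$sensitivity, lo$specificity), c(1, 0))
  hi <- contingency_at_threshold(scores, labels, 0.95)
  expect_equal(c(hi$sensitivity, hi$specificity), c(0, 1))
  # counts always sum to n and reproduce the ROC point
  set.seed(13)
  s <- round(runif(25), 2)
  l <- c(0, 1, sample(0:1, 23, replace = TRUE))
  r <- roc_curve(s, l)
  for (k in seq_along(r$thresholds)) {
    ct <- contingency_at_threshold(s, l, r$thresholds[k])
    expect_equal(ct$tp + ct$fn + ct$fp + ct$tn, 25)
    expect_equal(ct$sensitivity, r$tpr[k])
    expect_equal(1 - ct$specificity, r$fpr[k])
  }
})

test_that("threshold rules: fixed constant and Youden maximization", {
  scores <- c(0.1, 0.4, 0.6, 0.9)
  labels <- c(0, 0, 1, 1)
  expect_equal(choose_threshold(scores, labels, "fixed"), 0.5)
  expect_equal(choose_threshold(scores, labels, "youden"), 0.6)
  # separable: returned threshold is the lowest score above all negatives
  s2 <- c(0.2, 0.3, 0.7, 0.8, 0.9)
  l2 <- c(0, 0, 1, 1, 1)
  expect_equal(choose_threshold(s2, l2, "youden"), 0.7)
})

test_that("exact Mann-Whitney equals full permutation enumeration", {
  r <- mann_whitney_u(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(r$U, 0)
  expect_equal(r$p.value, 2 / 6)
  # 200 random tie-free instances vs the combn enumeration oracle
  # (n, m >= 3: below that the normal approximation is not meaningful)
  set.seed(14)
  for (rep in 1:200) {
    n <- sample(3:8, 1)
    m <- sample(3:8, 1)
    x <- rnorm(n)
    y <- rnorm(m, sample(c(0, 1), 1))
    mine <- mann_whitney_u(x, y, mode = "exact")
    expect_equal(mine$p.value, mw_exact_enum(x, y), tolerance = 1e-12)
    # and against the normal approximation, which must be close
    approx <- mann_whitney_u(x, y, mode = "normal")
    expect_lt(abs(mine$p.value - approx$p.value), 0.05)
  }
})

test_that("exact Mann-Whitney matches wilcox.test across sizes", {
  set.seed(15)
  for (rep in 1:40) {
    n <- sample(3:10, 1)
    m <- sample(3:25, 1)
    x <- rnorm(n)
    y <- rnorm(m, 0.5)
    mine <- mann_whitney_u(x, y, mode = "exact")
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("identical samples give p near 1 in normal mode", {
  x <- c(3, 1, 4, 1, 5)
  r <- mann_whitney_u(x, x, mode = "normal")
  expect_gte(r$p.value, 0.99)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("compound screen reports raw p plus BH q per feature", {
  tab <- tiny_table(n_kd = 15, n_fc = 15, n_compounds = 8,
                    n_informative = 2, effect_size = 3, seed = 19)
  res <- compound_tests(tab)
  expect_equal(nrow(res), 24)
  expect_true(all(res$channel %in% c("R", "G", "B")))
  expect_equal(res$q, p.adjust(res$p, "BH"))
  co <- tiny_cohort(n_kd = 15, n_fc = 15, n_compounds = 8,
                    n_informative = 2, effect_size = 3, seed = 19)
  inf_r <- paste0(co$compounds[co$informative], "_R")
  expect_lt(max(res$p[res$feature %in% inf_r]), 0.01)
})
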