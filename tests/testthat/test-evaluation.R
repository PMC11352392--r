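test_that("confusion metrics match the closed forms", {
  m <- confusion_metrics(50, 0, 50, 0)
  expect_equal(unlist(m), c(acc = 1, sen = 1, spe = 1))
  m2 <- confusion_metrics(30, 10, 40, 20)
  expect_equal(m2$acc, 0.70)
  expect_equal(m2$sen, 0.75)
  expect_equal(m2$spe, 2 / 3, tolerance = 1e-12)
  m3 <- confusion_metrics(0, 5, 5, 0)
  expect_equal(unlist(m3), c(acc = 0.5, sen = 0, spe = 1))
  expect_error(confusion_metrics(0, 0, 3, 1), "sensitivity")
  expect_error(confusion_metrics(3, 1, 0, 0), "specificity")
  # identities hold for random integer counts
  set.seed(31)
  for (rep in 1:50) {
    cts <- rpois(4, 10) + c(1, 0, 1, 0)
    m <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(m$acc, (cts[1] + cts[3]) / sum(cts))
    expect_equal(m$sen, cts[1] / (cts[1] + cts[2]))
    expect_equal(m$spe, cts[3] / (cts[3] + cts[4]))
  }
})

test_that("rank AUC equals the Mann-Whitney statistic", {
  set.seed(32)
  for (rep in 1:20) {
    scores <- rnorm(30)
    pos <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(pos) || all(pos)) next
    w <- stats::wilcox.test(scores[pos], scores[!pos], exact = FALSE)
    expect_equal(auc_rank(scores, pos),
                 unname(w$statistic) / (sum(pos) * sum(!pos)))
  }
  expect_equal(auc_rank(c(3, 2, 1), c(TRUE, TRUE, FALSE)), 1)
})

test_that("pairwise SVM separates planted subtypes and is honest under permutation", {
  sim <- small_cohort(seed = 41, n_case = 60, n_subtypes = 2,
                      effect_size = 4)
  feats <- group_values(sim$features, "case")
  res <- pairwise_svm_cv(feats, sim$truth, n_folds = 5, seed = 1)
  expect_equal(res$pairs$acc, 1)
  expect_equal(res$pairs$auc, 1)
  # permuted labels: near-chance accuracy
  set.seed(2)
  zperm <- sample(sim$truth)
  resp <- pairwise_svm_cv(feats, zperm, n_folds = 5, seed = 1)
  expect_lt(abs(resp$pairs$acc - 0.5), 0.2)
  # determinism
  res2 <- pairwise_svm_cv(feats, sim$truth, n_folds = 5, seed = 1)
  expect_identical(res$pairs, res2$pairs)
  # tiny subtypes are skipped with a reason
  z3 <- sim$truth; z3[1] <- 99L
  res3 <- pairwise_svm_cv(feats, z3, n_folds = 5, seed = 1)
  expect_true(length(res3$skipped) >= 1)
})

test_that("averaged metrics are the unweighted mean over pairs", {
  sim <- small_cohort(seed = 42, n_case = 60, n_subtypes = 3,
                      effect_size = 3)
  feats <- group_values(sim$features, "case")
  res <- suppressWarnings(pairwise_svm_cv(feats, sim$truth, n_folds = 5,
                                          seed = 3))
  expect_equal(nrow(res$pairs), 3L)
  expect_equal(res$average$acc, mean(res$pairs$acc))
  expect_equal(res$average$auc, mean(res$pairs$auc))
})

test_that("adjusted group difference reduces to the classical t-test", {
  # identical group means: t = 0, p = 1
  y <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("case", "control"), each = 3)
  r0 <- adjusted_group_difference(matrix(y, ncol = 1), g)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # (1,2,3) vs (4,5,6): equal-variance two-sample t = -3.674 on 4 df
  y1 <- c(1, 2, 3, 4, 5, 6)
  r1 <- adjusted_group_difference(matrix(y1, ncol = 1), g)
  tt <- stats::t.test(y1[1:3], y1[4:6], var.equal = TRUE)
  expect_equal(r1$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r1$p, tt$p.value, tolerance = 1e-10)
  expect_equal(round(r1$t, 3), -3.674)
  expect_equal(r1$direction, "case<control")
  # a covariate orthogonal to group leaves the group t unchanged
  covar <- c(-1, 0, 1, -1, 0, 1)   # balanced across groups, orthogonal
  y2 <- y1 + 0.5 * covar
  r2a <- adjusted_group_difference(matrix(y2, ncol = 1), g,
                                   data.frame(c1 = covar))
  y2_resid <- y2 - 0.5 * covar
  r2b <- adjusted_group_difference(matrix(y2_resid, ncol = 1), g)
  expect_equal(r2a$estimate, r2b$estimate, tolerance = 1e-10)
})

test_that("rank-deficient designs fail loudly with the aliased column", {
  y <- matrix(rnorm(8), ncol = 1)
  g <- rep(c("case", "control"), each = 4)
  site <- rep(c("s1", "s2"), each = 4)   # confounded with group
  expect_error(adjusted_group_difference(y, g, data.frame(site = site)),
               "aliased")
  expect_error(adjusted_group_difference(y[1:5, , drop = FALSE],
                                         c("case", "case", rep("control", 3))),
               "at least 3")
})

test_that("BH step-up matches hand values and the reference implementation", {
  r <- fdr_bh(c(0.01, 0.02, 0.04, 0.05))
  expect_equal(r$q, c(0.04, 0.04, 0.05, 0.05))
  expect_equal(fdr_bh(rep(0.03, 5))$q, rep(0.03, 5))
  expect_equal(fdr_bh(0.2)$q, 0.2)
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(33)
  for (rep in 1:1000) {
    p <- runif(sample(1:20, 1))
    expect_equal(fdr_bh(p)$q, stats::p.adjust(p, "BH"))
  }
})

test_that("subtype_profile recovers planted region blocks", {
  sim <- small_cohort(seed = 43, n_case = 60, n_control = 60,
                      n_subtypes = 2, effect_size = 4)
  prof <- subtype_profile(sim$features, sim$truth)
  expect_named(prof, c("subtype1", "subtype2"))
  # subtype 1 shifts regions 1-10, subtype 2 regions 11-20, both upward
  sig1 <- which(prof$subtype1$significant)
  sig2 <- which(prof$subtype2$significant)
  expect_true(all(1:10 %in% sig1))
  expect_true(all(11:20 %in% sig2))
  expect_true(all(prof$subtype1$direction[1:10] == "case>control"))
  # disjoint planted blocks give (essentially) disjoint significant sets
  expect_lt(length(intersect(sig1, sig2)), 3)
  # an empty subtype is skipped with a message
  z <- sim$truth; z[z == 2] <- 1; z[1:2] <- 2
  expect_message(p2 <- subtype_profile(sim$features, z), "skipped")
  expect_named(p2, "subtype1")
})
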