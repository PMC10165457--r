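test_that("random-forest ranking finds a strongly separating feature", {
  set.seed(9)
  n <- 40
  mat <- matrix(rnorm(51 * n), nrow = 51)
  groups <- rep(c("A", "B"), each = n / 2)
  mat[1, groups == "B"] <- mat[1, groups == "B"] + 3  # 3-SD planted shift
  st <- make_site_table(mat, groups, scale = "log2")
  rk <- rf_importance(st, top_k = 5, seed = 21)
  expect_equal(rk$site_id[1], "P1-S1")
  expect_true(all(diff(rk$importance) <= 0))
  # determinism under a fixed seed
  expect_identical(rf_importance(st, top_k = 5, seed = 21), rk)
  one_class <- make_site_table(mat[, 1:5], rep("A", 5), scale = "log2")
  expect_error(rf_importance(one_class), "2 groups")
})

test_that("pure-noise permutation importances centre on zero", {
  imp1 <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    mat <- matrix(rnorm(20 * 30), nrow = 20)  # fresh null data each replicate
    st <- make_site_table(mat, rep(c("A", "B"), each = 15), scale = "log2")
    rk <- rf_importance(st, top_k = 20, num_trees = 100, seed = s)
    rk$importance[match("P1-S1", rk$site_id)]
  }, numeric(1))
  # sign test: under the null a feature's permutation importance is positive
  # about as often as negative across independent datasets
  p <- binom.test(sum(imp1 > 0), length(imp1))$p.value
  expect_gt(p, 0.001)
  expect_lt(abs(mean(imp1)), 0.05)
})

test_that("rank AUC equals the brute-force concordant-pair count and pROC", {
  set.seed(13)
  for (i in 1:20) {
    pos <- rnorm(7); neg <- rnorm(9)
    if (i %% 3 == 0) pos[1] <- neg[1]  # exercise ties
    got <- phosphoDIA:::rank_auc(pos, neg)
    expect_equal(got, pair_count_auc(pos, neg), tolerance = 1e-12)
  }
  lab <- rep(c(0, 1), c(9, 7))
  sc <- c(rnorm(9), rnorm(7, 1))
  expect_equal(phosphoDIA:::rank_auc(sc[lab == 1], sc[lab == 0]),
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("panel AUC is 1 for perfect separation and ~0.5 for noise", {
  set.seed(19)
  groups <- rep(c("A", "B"), each = 30)
  sep <- rbind(c(rep(0, 30), rep(5, 30)) + rnorm(60, sd = 0.1),
               rnorm(60))
  st <- make_site_table(sep, groups, scale = "log2")
  expect_equal(multiclass_auc(st, "P1-S1"), 1)
  # resubstitution scoring for the null calibration: leave-one-out scores of
  # a label-independent feature are biased below 0.5 by construction
  auc_null <- multiclass_auc(st, "P2-S2", cv = "none")
  expect_lt(abs(auc_null - 0.5), 0.1)
  bad <- make_site_table(sep[, c(1, 31)], groups[c(1, 31)], scale = "log2")
  expect_error(multiclass_auc(bad, "P1-S1"), "at least 2 samples")
  expect_error(multiclass_auc(st, "nope"), "unknown features")
})

test_that("multiclass AUC averages pairwise class AUCs (Hand-Till)", {
  set.seed(4)
  groups <- rep(c("A", "B", "C"), each = 12)
  mat <- rbind(c(rnorm(12, 0), rnorm(12, 4), rnorm(12, 8)) * 0.5,
               rnorm(36))
  st <- make_site_table(mat, groups, scale = "log2")
  a <- multiclass_auc(st, c("P1-S1", "P2-S2"))
  expect_gt(a, 0.9)
  expect_lte(a, 1)
  # resubstitution is at least as optimistic as leave-one-out here
  expect_gte(multiclass_auc(st, c("P1-S1", "P2-S2"), cv = "none") + 1e-9, a)
})

test_that("expected AUC does not decrease with planted effect size", {
  # the expectation over replicates is monotone; single replicates are not,
  # because the fitted discriminant direction can flip at tiny effects
  groups <- rep(c("A", "B"), each = 15)
  mean_aucs <- vapply(c(0, 0.5, 1, 2, 4), function(eff) {
    mean(vapply(1:40, function(s) {
      set.seed(100 + s)  # common noise across the effect grid
      m <- rbind(rnorm(30) + ifelse(groups == "B", eff, 0))
      multiclass_auc(make_site_table(m, groups, scale = "log2"), "P1-S1",
                     cv = "none")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_aucs) > 0))
})

test_that("LDA projects three groups onto two discriminating axes", {
  set.seed(12)
  groups <- rep(c("A", "B", "C"), each = 15)
  centres <- rbind(c(0, 0, 6), c(0, 6, 0), c(0, 6, 6), c(1, 1, 1))
  mat <- centres[, match(groups, c("A", "B", "C"))] +
    matrix(rnorm(4 * 45, sd = 0.4), nrow = 4)
  st <- make_site_table(mat, groups, scale = "log2")
  proj <- lda_project(st)
  expect_equal(ncol(proj$scaling), 2)
  expect_equal(names(proj$coordinates), c("sample_id", "group", "LD1", "LD2"))
  sil <- cluster::silhouette(as.integer(factor(proj$coordinates$group)),
                             dist(proj$coordinates[, c("LD1", "LD2")]))
  expect_gt(mean(sil[, 3]), 0.5)
  # axis sign convention: dominant loading is positive
  expect_true(all(apply(proj$scaling, 2, function(v) v[which.max(abs(v))] > 0)))
})

test_that("LDA axes equal principal axes of class means under isotropic scatter", {
  set.seed(3)
  groups <- rep(c("A", "B", "C"), each = 200)
  centres <- cbind(A = c(0, 0), B = c(4, 0), C = c(0, 2))
  mat <- centres[, match(groups, colnames(centres))] +
    matrix(rnorm(2 * 600, sd = 1), nrow = 2)   # within-scatter ~ identity
  st <- make_site_table(mat, groups, scale = "log2")
  proj <- lda_project(st)
  B <- tcrossprod(sweep(centres, 1, rowMeans(centres)))
  pa <- eigen(B, symmetric = TRUE)$vectors
  for (k in 1:2) {
    v <- proj$scaling[, k] / sqrt(sum(proj$scaling[, k]^2))
    expect_gt(abs(sum(v * pa[, k])), 0.98)     # aligned up to sign
  }
})

test_that("LDA subspace matches MASS::lda and survives global shifts", {
  set.seed(14)
  groups <- rep(c("A", "B", "C"), each = 10)
  mat <- matrix(rnorm(5 * 30), nrow = 5)
  mat[1, ] <- mat[1, ] + c(A = 0, B = 3, C = 6)[groups]
  mat[2, ] <- mat[2, ] + c(A = 0, B = 0, C = 3)[groups]
  st <- make_site_table(mat, groups, scale = "log2")
  proj <- lda_project(st)
  mf <- MASS::lda(t(mat), grouping = groups)
  # the spanned discriminant subspaces agree: principal angles ~ 0
  qa <- qr.Q(qr(proj$scaling))
  qb <- qr.Q(qr(mf$scaling))
  ang <- svd(crossprod(qa, qb))$d
  expect_equal(ang, c(1, 1), tolerance = 1e-6)
  # a uniform shift of all samples leaves axes and shape unchanged
  shifted <- st
  shifted$abundance <- st$abundance + 2.5
  proj2 <- lda_project(shifted)
  expect_equal(proj2$scaling, proj$scaling, tolerance = 1e-8)
  expect_equal(diff(proj2$coordinates$LD1), diff(proj$coordinates$LD1),
               tolerance = 1e-8)
})

test_that("singular within-class scatter falls back to shrinkage with a warning", {
  set.seed(6)
  groups <- rep(c("A", "B", "C"), each = 4)
  mat <- matrix(rnorm(30 * 12), nrow = 30)  # features >> samples
  mat[1, ] <- mat[1, ] + c(A = 0, B = 4, C = 8)[groups]
  st <- make_site_table(mat, groups, scale = "log2")
  expect_warning(proj <- lda_project(st), "shrinkage")
  expect_gt(proj$shrinkage, 0)
  expect_equal(ncol(proj$scaling), 2)
})
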