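test_that("QC floor blanks strictly sub-floor cells only", {
  m <- matrix(c(29.9, 30, 45, 10), 2, 2,
              dimnames = list(c("r1", "r2"), c("a", "b")))
  out <- qc_floor(m, 30)
  expect_true(is.na(out["r1", "a"]))
  expect_equal(out["r2", "a"], 30)          # boundary kept
  expect_true(is.na(out["r2", "b"]))
  ok <- matrix(c(50, 60, 70, 80), 2, 2)
  expect_equal(qc_floor(ok), ok)            # all cells at/above floor untouched
  st <- make_site_table(matrix(5, 2, 4), rep("g", 4), scale = "log2")
  expect_error(qc_floor(st), "raw-scale")
})

test_that("log2 transform is elementwise and preserves missingness", {
  m <- matrix(c(1024, 30, NA, 2), 2, 2)
  out <- log2_transform(m)
  expect_equal(out[1, 1], 10)
  expect_equal(out[2, 1], log2(30), tolerance = 1e-10)
  expect_true(is.na(out[1, 2]))
  expect_error(log2_transform(matrix(c(-1, 2), 1, 2)), "nonpositive")
})

test_that("normality gate has the nominal type-I rate on normal samples", {
  set.seed(401)
  mat <- matrix(rnorm(100 * 200), nrow = 100)
  st <- make_site_table(mat, rep("g", 200), scale = "log2")
  g <- sample_normality_gate(st, alpha = 0.01)
  frac <- mean(g$report$status == "excluded")
  expect_lt(frac, 0.04)   # ~1% expected; binomial slack at 200 samples
})

test_that("normality gate rejects heavy bimodality and honours alpha 0", {
  set.seed(7)
  mat <- matrix(rnorm(100 * 6, 10), nrow = 100)
  mat[, 6] <- c(rnorm(50, 4), rnorm(50, 16))  # planted bimodal sample
  st <- make_site_table(mat, rep("g", 6), scale = "log2")
  g <- sample_normality_gate(st, alpha = 0.01)
  expect_equal(g$report$status[6], "excluded")
  expect_equal(ncol(g$table$abundance), 5)
  g0 <- sample_normality_gate(st, alpha = 0)
  expect_true(all(g0$report$status == "kept"))
  # too few observed values is flagged untestable, not excluded
  small <- make_site_table(matrix(rnorm(5 * 3), nrow = 5), rep("g", 3),
                           scale = "log2")
  gs <- sample_normality_gate(small)
  expect_true(all(gs$report$status == "untestable"))
})

test_that("completeness keeps sites with more than 70% observed in one group", {
  m <- matrix(NA_real_, 3, 28)
  m[1, ] <- 1                      # fully observed
  m[2, 1:10] <- 1                  # 10/14 = 71.4% in group A only
  m[3, c(1:9, 15:24)] <- 1         # 64% in A but 71.4% in B: kept
  st <- make_site_table(m, rep(c("A", "B"), each = 14), scale = "log2")
  out <- group_completeness_filter(st, "A", "B", 0.70)
  expect_true(all(c("P1-S1", "P2-S2") %in% rownames(out$abundance)))
  # exactly 70% in both groups (7/10) is dropped: strict inequality
  m2 <- matrix(NA_real_, 1, 20)
  m2[1, c(1:7, 11:17)] <- 1
  st2 <- make_site_table(m2, rep(c("A", "B"), each = 10), scale = "log2")
  out2 <- group_completeness_filter(st2, "A", "B", 0.70)
  expect_equal(nrow(out2$abundance), 0)
  expect_error(group_completeness_filter(st2, "A", "C"), "empty group")
})

test_that("downshift imputation draws from the shifted normal and is seeded", {
  set.seed(88)
  n <- 20000
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "s1"))
  x[sample(n, n / 5), 1] <- NA
  obs <- x[!is.na(x), 1]
  out <- impute_downshift(x, seed = 5)
  imp <- out[is.na(x[, 1]), 1]
  expect_equal(mean(imp), mean(obs) - 1.8 * sd(obs), tolerance = 0.02)
  expect_equal(sd(imp), 0.3 * sd(obs), tolerance = 0.01)
  # observed cells untouched; rerun identical; no-missing identity
  expect_identical(out[!is.na(x[, 1]), 1], obs)
  expect_identical(impute_downshift(x, seed = 5), out)
  full <- matrix(rnorm(10), ncol = 1, dimnames = list(NULL, "s1"))
  expect_identical(impute_downshift(full, seed = 1), full)
  thin <- matrix(c(1, NA, NA), ncol = 1, dimnames = list(NULL, "s1"))
  expect_error(impute_downshift(thin), "fewer than 2")
})

test_that("median normalization equalises sample medians and keeps contrasts", {
  m <- matrix(c(9, 10, 11, 11, 12, 13), 3, 2)
  colnames(m) <- c("a", "b")
  out <- median_normalize(m)
  expect_equal(unname(apply(out, 2, median)), c(11, 11))
  # within-sample differences are untouched by the affine shift
  expect_equal(diff(out[, 1]), diff(m[, 1]))
  same <- matrix(c(1, 2, 3, 0, 2, 4), 3, 2)
  expect_equal(median_normalize(same), same)  # equal medians: identity
})

test_that("Welch statistics match the closed-form example and the t.test oracle", {
  st <- make_site_table(rbind(c(1, 2, 3, 2, 3, 4)),
                        rep(c("A", "B"), each = 3), scale = "log2")
  res <- welch_volcano(st, "A", "B")
  expect_equal(res$t_statistic, -sqrt(1.5), tolerance = 1e-10)  # -1.224745
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(-sqrt(1.5), 4), tolerance = 1e-12)
  expect_equal(round(res$p_value, 3), 0.288)
  # oracle: stats::t.test over 100 random small instances
  set.seed(202)
  for (i in 1:100) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    xa <- rnorm(na); xb <- rnorm(nb, sd = runif(1, 0.5, 2))
    sti <- make_site_table(rbind(c(xa, xb)),
                           rep(c("A", "B"), c(na, nb)), scale = "log2")
    got <- welch_volcano(sti, "A", "B")
    tt <- t.test(xa, xb)
    expect_equal(got$t_statistic, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(tt$parameter), tolerance = 1e-10)
    expect_equal(got$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("volcano classes follow the joint p and fold-change rule", {
  # strong planted shifts versus a flat site and a degenerate site
  set.seed(33)
  up <- rnorm(10, sd = 0.05); up[1:5] <- up[1:5] + 2
  flat <- rnorm(10, sd = 0.05)
  zero <- rep(1, 10)
  st <- make_site_table(rbind(up, flat, zero), rep(c("A", "B"), each = 5),
                        scale = "log2")
  res <- welch_volcano(st, "A", "B")
  expect_equal(res$volcano_class, c("up", "not_significant", "not_significant"))
  expect_equal(res$p_value[3], 1)  # zero variance, equal means
  # identical groups: difference 0, never significant
  same <- make_site_table(rbind(rep(1:5, 2)), rep(c("A", "B"), each = 5),
                          scale = "log2")
  expect_equal(welch_volcano(same, "A", "B")$log2_difference, 0)
  # classification invariant on a random table
  sim <- make_site_table(matrix(rnorm(200 * 12), 200), rep(c("A", "B"), 6),
                         scale = "log2")
  r <- welch_volcano(sim, "A", "B")
  expect_identical(r$volcano_class == "up",
                   r$p_value <= 0.05 & r$log2_difference >= 0.5)
  expect_identical(r$volcano_class == "down",
                   r$p_value <= 0.05 & r$log2_difference <= -0.5)
})

test_that("pipeline stage order matters and is fixed", {
  sim <- simulate_report(simulation_config(n_sites = 250, seed = 15))
  st <- log2_transform(qc_floor(collapse_to_sites(class1_filter(sim$records))))
  st <- sample_normality_gate(st)$table
  sub <- group_completeness_filter(st, "high_grade", "HC")
  canonical <- welch_volcano(median_normalize(impute_downshift(sub, seed = 4)),
                             "high_grade", "HC")
  swapped <- welch_volcano(impute_downshift(median_normalize(sub), seed = 4),
                           "high_grade", "HC")
  # normalizing before imputing changes the imputation reference and results
  expect_false(isTRUE(all.equal(canonical$p_value, swapped$p_value)))
  # regression: canonical order is reproducible
  again <- welch_volcano(median_normalize(impute_downshift(sub, seed = 4)),
                         "high_grade", "HC")
  expect_identical(canonical, again)
})

test_that("Wilcoxon marker selection requires elevation against every group", {
  set.seed(50)
  groups <- rep(c("HC", "CKD", "low_grade", "high_grade"), each = 10)
  base <- matrix(rnorm(3 * 40, 10, 0.3), nrow = 3)
  base[1, groups == "high_grade"] <- base[1, groups == "high_grade"] + 2
  base[3, groups %in% c("low_grade", "high_grade")] <-
    base[3, groups %in% c("low_grade", "high_grade")] + 2
  st <- make_site_table(base, groups, scale = "log2")
  sel_high <- heatmap_marker_selection(st, "high_grade")
  expect_true("P1-S1" %in% sel_high)              # planted high-grade marker
  expect_false("P2-S2" %in% sel_high)             # flat site
  # equally elevated in both grades fails the low-vs-high comparison ...
  expect_false("P3-S3" %in% sel_high)
  expect_false("P3-S3" %in% heatmap_marker_selection(st, "low_grade"))
  # ... but passes under the any-comparison rule
  expect_true("P3-S3" %in% heatmap_marker_selection(st, "high_grade",
                                                    mode = "any"))
  tiny <- make_site_table(base[, 1:12], groups[1:12], scale = "log2")
  expect_error(heatmap_marker_selection(tiny, "HC"), "at least 3")
})
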