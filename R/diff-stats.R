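#' Quality-control intensity floor
#'
#' Raw intensities below the floor (default 30) are unreliable peak-area
#' integrations and are converted to missing; values equal to the floor
#' are kept ("below" is strict).
#'
#' @param x a raw-scale `site_table` or numeric matrix.
#' @param floor intensity floor, default 30.
#' @return Object of the same kind with sub-floor cells set to `NA`.
#' @export
qc_floor <- function(x, floor = 30) {
  assert_number(floor, "floor")
  if (inherits(x, "site_table")) {
    if (x$scale != "raw") stop2("qc_floor applies to raw-scale tables only")
    abn <- x$abundance
    abn[!is.na(abn) & abn < floor] <- NA_real_
    return(set_abundance(x, abn))
  }
  stopifnot(is.matrix(x))
  x[!is.na(x) & x < floor] <- NA_real_
  x
}

#' Log2-transform raw abundances
#'
#' @param x a raw-scale `site_table` or numeric matrix of positive values
#'   (apply [qc_floor()] first); missing cells stay missing.
#' @return The log2-scale object.
#' @export
log2_transform <- function(x) {
  if (inherits(x, "site_table")) {
    if (x$scale != "raw") stop2("table is already on the log2 scale")
    abn <- x$abundance
    if (any(abn <= 0, na.rm = TRUE)) stop2("nonpositive intensities cannot be log2-transformed")
    return(set_abundance(x, log2(abn), scale = "log2"))
  }
  stopifnot(is.matrix(x))
  if (any(x <= 0, na.rm = TRUE)) stop2("nonpositive intensities cannot be log2-transformed")
  log2(x)
}

#' Per-sample normality gate
#'
#' Downstream Welch testing assumes approximately normal log2 abundance
#' distributions per sample; samples whose observed distribution fails a
#' normality test at `alpha` are excluded and reported. The test defaults
#' to Shapiro-Wilk and is user-configurable; samples with fewer than 8
#' observed values are flagged untestable and retained.
#'
#' The gate screens for gross distributional failure (failed runs, bimodal
#' mixtures), not for the mild left-truncation that intensity-dependent
#' missingness imposes on every label-free sample -- a deviation a
#' goodness-of-fit test at thousands of values would flag in all samples.
#' The test is therefore evaluated on a deterministic order-preserving
#' subsample of at most `max_n` values (default 100), which keeps
#' essentially full power against gross departures.
#'
#' @param st a log2-scale `site_table`.
#' @param alpha exclusion level, default 0.01; `alpha = 0` excludes nothing.
#' @param test function taking a numeric vector and returning an object
#'   with a `p.value` (default [stats::shapiro.test()]).
#' @param max_n cap on the number of values entering the test, default 100.
#' @return List with `table` (retained samples) and `report` (data frame:
#'   `sample_id`, `n_observed`, `p_value`, `status` of kept / excluded /
#'   untestable).
#' @export
sample_normality_gate <- function(st, alpha = 0.01, test = stats::shapiro.test,
                                  max_n = 100L) {
  stopifnot(inherits(st, "site_table"))
  if (st$scale != "log2") stop2("normality gate expects a log2-scale table")
  assert_number(alpha, "alpha", lower = 0, upper = 1)
  res <- lapply(seq_len(ncol(st$abundance)), function(j) {
    v <- st$abundance[, j]
    v <- v[!is.na(v)]
    if (length(v) < 8L)
      return(data.frame(n_observed = length(v), p_value = NA_real_,
                        status = "untestable"))
    if (length(v) > max_n)
      v <- sort(v)[round(seq(1L, length(v), length.out = max_n))]
    p <- test(v)$p.value
    data.frame(n_observed = length(v), p_value = p,
               status = if (p < alpha) "excluded" else "kept")
  })
  report <- cbind(data.frame(sample_id = st$samples$sample_id), do.call(rbind, res))
  keep <- report$sample_id[report$status != "excluded"]
  if (length(keep) == 0L)
    stop2("every sample failed the normality gate; inspect the report with alpha = 0")
  list(table = subset_samples(st, keep), report = report)
}

#' Group completeness filter for a two-group comparison
#'
#' Keeps a site iff its observed (non-missing) fraction is strictly greater
#' than `fraction` in at least one of the two groups -- "more than 70%
#' quantified in at least one category" at the default.
#'
#' @param st a `site_table`.
#' @param group_a,group_b the two group labels of the comparison.
#' @param fraction completeness threshold, default 0.70 (strict `>`).
#' @return A `site_table` restricted to the two groups' samples and the
#'   surviving sites.
#' @export
group_completeness_filter <- function(st, group_a, group_b, fraction = 0.70) {
  stopifnot(inherits(st, "site_table"))
  assert_number(fraction, "fraction", lower = 0, upper = 1)
  ids_a <- st$samples$sample_id[st$samples$group == group_a]
  ids_b <- st$samples$sample_id[st$samples$group == group_b]
  if (length(ids_a) == 0L || length(ids_b) == 0L)
    stop2("empty group in completeness filter: ",
          if (length(ids_a) == 0L) group_a else group_b)
  sub <- subset_samples(st, c(ids_a, ids_b))
  fr_a <- rowMeans(!is.na(sub$abundance[, ids_a, drop = FALSE]))
  fr_b <- rowMeans(!is.na(sub$abundance[, ids_b, drop = FALSE]))
  keep <- fr_a > fraction | fr_b > fraction
  set_abundance(sub, sub$abundance[keep, , drop = FALSE])
}

#' Downshifted-normal imputation of left-censored missing values
#'
#' Missing log2 abundances in label-free phosphoproteomics are concentrated
#' at low intensities, so they are imputed per sample from a normal
#' distribution shifted below the observed one: mean
#' `mean(observed) - downshift_sd * sd(observed)` and standard deviation
#' `width_sd * sd(observed)` (defaults 1.8 and 0.3, the Perseus
#' convention). Observed cells are untouched; draws are reproducible under
#' the seed.
#'
#' @param x a log2-scale `site_table` or numeric matrix (samples in columns).
#' @param downshift_sd downshift in observed-SD units, default 1.8.
#' @param width_sd imputed spread in observed-SD units, default 0.3.
#' @param seed integer seed for the draws.
#' @return The completed object.
#' @export
impute_downshift <- function(x, downshift_sd = 1.8, width_sd = 0.3, seed = 1L) {
  assert_number(downshift_sd, "downshift_sd")
  assert_number(width_sd, "width_sd")
  if (width_sd <= 0) stop2("'width_sd' must be positive")
  mat <- if (inherits(x, "site_table")) {
    if (x$scale != "log2") stop2("imputation expects a log2-scale table")
    x$abundance
  } else x
  stopifnot(is.matrix(mat))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  for (j in seq_len(ncol(mat))) {
    miss <- is.na(mat[, j])
    if (!any(miss)) next
    obs <- mat[!miss, j]
    if (length(obs) < 2L)
      stop2("sample ", colnames(mat)[j] %||% j,
            " has fewer than 2 observed values; cannot impute")
    mu <- mean(obs) - downshift_sd * stats::sd(obs)
    sigma <- width_sd * stats::sd(obs)
    mat[miss, j] <- stats::rnorm(sum(miss), mu, sigma)
  }
  if (inherits(x, "site_table")) set_abundance(x, mat) else mat
}

#' Median-normalize samples
#'
#' Shifts each sample's log2 values so all per-sample medians equal the
#' grand median of sample medians, keeping values on the original
#' intensity scale. An affine shift: within-sample differences, and hence
#' all downstream test statistics, are unchanged by the choice of target.
#'
#' @param x a complete log2-scale `site_table` or numeric matrix.
#' @return The normalized object.
#' @export
median_normalize <- function(x) {
  mat <- if (inherits(x, "site_table")) {
    if (x$scale != "log2") stop2("median normalization expects a log2-scale table")
    x$abundance
  } else x
  stopifnot(is.matrix(mat))
  med <- apply(mat, 2, stats::median, na.rm = TRUE)
  target <- stats::median(med)
  mat <- sweep(mat, 2, med - target)
  if (inherits(x, "site_table")) set_abundance(x, mat) else mat
}

# vectorised Welch statistics over matrix rows; xa, xb complete matrices
welch_rows <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  # both groups constant: no evidence either way
  degenerate <- se2 == 0
  tt[degenerate] <- 0
  df[degenerate] <- na + nb - 2
  p[degenerate] <- 1
  data.frame(log2_difference = ma - mb, t_statistic = tt, df = df, p_value = p)
}

#' Welch volcano classification of phosphosites
#'
#' Per site, a Welch (unequal-variance) two-sample t test of `group_a`
#' minus `group_b` on the completed, normalized log2 table, with
#' Satterthwaite degrees of freedom and a two-sided p-value. Sites are
#' classed `up` when `p <= p_cutoff` and `log2_difference >= lfc_cutoff`
#' (default 0.05 and 0.5, i.e. ~1.414-fold), `down` symmetrically, else
#' `not_significant`. Raw p-values are used for classification, matching
#' common volcano practice; an optional Benjamini-Hochberg adjusted column
#' is reported alongside.
#'
#' @param st a complete log2-scale `site_table`.
#' @param group_a,group_b group labels; the difference is A minus B.
#' @param p_cutoff,lfc_cutoff volcano cutoffs (defaults 0.05, 0.5).
#' @param adjust add a `p_adjusted` (BH) column; classification still uses
#'   raw p unless `classify_adjusted = TRUE`.
#' @param classify_adjusted classify on BH-adjusted p-values instead.
#' @return Data frame: site annotation plus `log2_difference`,
#'   `t_statistic`, `df`, `p_value`, (`p_adjusted`,) `volcano_class`.
#' @export
welch_volcano <- function(st, group_a, group_b, p_cutoff = 0.05,
                          lfc_cutoff = 0.5, adjust = FALSE,
                          classify_adjusted = FALSE) {
  stopifnot(inherits(st, "site_table"))
  if (st$scale != "log2") stop2("welch_volcano expects a log2-scale table")
  ids_a <- st$samples$sample_id[st$samples$group == group_a]
  ids_b <- st$samples$sample_id[st$samples$group == group_b]
  if (length(ids_a) < 2L || length(ids_b) < 2L)
    stop2("both groups need at least 2 samples")
  xa <- st$abundance[, ids_a, drop = FALSE]
  xb <- st$abundance[, ids_b, drop = FALSE]
  if (anyNA(xa) || anyNA(xb))
    stop2("table contains missing values; impute before testing")
  res <- welch_rows(xa, xb)
  out <- cbind(st$sites[, intersect(c("site_id", "protein_accession", "residue",
                                      "position"), names(st$sites))], res)
  pcl <- res$p_value
  if (adjust || classify_adjusted) {
    out$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
    if (classify_adjusted) pcl <- out$p_adjusted
  }
  out$volcano_class <- ifelse(
    pcl <= p_cutoff & res$log2_difference >= lfc_cutoff, "up",
    ifelse(pcl <= p_cutoff & res$log2_difference <= -lfc_cutoff, "down",
           "not_significant"))
  rownames(out) <- NULL
  out
}

#' Wilcoxon heatmap marker selection
#'
#' Selects, for a target group, the sites elevated in that group against
#' each of the other groups of a four-group design: unpaired two-sample
#' Wilcoxon rank-sum `p <= p_cutoff` (default 0.1) with a positive shift in
#' the target group for every pairwise comparison (`mode = "all"`), or for
#' at least one (`mode = "any"`).
#'
#' @param st a complete log2-scale `site_table` with >= 2 groups.
#' @param target_group the group whose markers are sought.
#' @param p_cutoff Wilcoxon p cutoff, default 0.1 (`<=`).
#' @param mode `"all"` (default) or `"any"` comparisons rule.
#' @return Character vector of selected `site_id`s.
#' @export
heatmap_marker_selection <- function(st, target_group, p_cutoff = 0.1,
                                     mode = c("all", "any")) {
  mode <- match.arg(mode)
  stopifnot(inherits(st, "site_table"))
  groups <- unique(st$samples$group)
  if (!target_group %in% groups) stop2("unknown target group: ", target_group)
  others <- setdiff(groups, target_group)
  sizes <- table(st$samples$group)
  if (any(sizes < 3)) stop2("all groups need at least 3 samples")
  ids_t <- st$samples$sample_id[st$samples$group == target_group]
  xt <- st$abundance[, ids_t, drop = FALSE]
  hits <- matrix(FALSE, nrow = nrow(st$abundance), ncol = length(others))
  for (k in seq_along(others)) {
    ids_o <- st$samples$sample_id[st$samples$group == others[k]]
    xo <- st$abundance[, ids_o, drop = FALSE]
    for (i in seq_len(nrow(xt))) {
      p <- suppressWarnings(
        stats::wilcox.test(xt[i, ], xo[i, ], exact = FALSE)$p.value)
      hits[i, k] <- !is.na(p) && p <= p_cutoff &&
        stats::median(xt[i, ]) > stats::median(xo[i, ])
    }
  }
  sel <- if (mode == "all") rowSums(hits) == length(others) else rowSums(hits) > 0
  st$sites$site_id[sel]
}
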