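#' Random-forest permutation-importance feature ranking
#'
#' Ranks candidate phosphosites (typically the volcano-up sites of a
#' comparison) by permutation importance from a seeded random forest
#' (ranger, 500 trees, sqrt-features per split by default) and returns the
#' top k. Deterministic given the seed.
#'
#' @param st a complete log2-scale `site_table` restricted to candidate sites.
#' @param groups optional subset of group labels to classify (default all).
#' @param top_k number of features to return, default 15 (or all if fewer).
#' @param num_trees forest size, default 500.
#' @param seed integer seed.
#' @return Data frame `rank`, `site_id`, `importance`, descending.
#' @export
rf_importance <- function(st, groups = NULL, top_k = 15, num_trees = 500,
                          seed = 1L) {
  stopifnot(inherits(st, "site_table"))
  samp <- st$samples
  if (!is.null(groups)) samp <- samp[samp$group %in% groups, , drop = FALSE]
  if (length(unique(samp$group)) < 2L)
    stop2("feature ranking needs at least 2 groups")
  x <- t(st$abundance[, samp$sample_id, drop = FALSE])
  dat <- as.data.frame(x)
  names(dat) <- paste0("f", seq_len(ncol(dat)))  # syntactic feature names
  dat$.group <- factor(samp$group)
  fit <- ranger::ranger(
    dependent.variable.name = ".group", data = dat,
    num.trees = num_trees, importance = "permutation",
    seed = seed, num.threads = 1L)
  imp <- fit$variable.importance
  ord <- order(-imp)
  k <- min(top_k, length(imp))
  data.frame(rank = seq_len(k),
             site_id = st$sites$site_id[ord][seq_len(k)],
             importance = unname(imp[ord])[seq_len(k)])
}

# rank-based AUC: P(score in positive group > score in negative) + ties/2
rank_auc <- function(score_pos, score_neg) {
  r <- rank(c(score_pos, score_neg), ties.method = "average")
  n1 <- length(score_pos); n2 <- length(score_neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# leave-one-out LDA posterior scores, one column per class
loo_lda_scores <- function(x, y) {
  n <- nrow(x)
  classes <- levels(y)
  scores <- matrix(NA_real_, nrow = n, ncol = length(classes),
                   dimnames = list(NULL, classes))
  for (i in seq_len(n)) {
    fit <- lda_fit(x[-i, , drop = FALSE], y[-i])
    scores[i, ] <- lda_posterior(fit, x[i, , drop = FALSE])
  }
  scores
}

#' Multiclass ROC AUC of a phosphosite feature panel
#'
#' Scores every sample with a linear-discriminant posterior for each class
#' -- leave-one-out cross-validated by default, or resubstitution (noted as
#' optimistic) -- and reports the area under the ROC curve. For two groups
#' this is the standard rank-based AUC; for more, the Hand-Till multiclass
#' AUC: the average over all class pairs (i, j) of
#' `(A(i|j) + A(j|i)) / 2`, each term a rank AUC of the class-i posterior
#' over samples of classes i and j.
#'
#' @param st a complete log2-scale `site_table`.
#' @param features character vector of `site_id`s forming the panel.
#' @param groups optional subset of groups (default all in the table).
#' @param cv `"loo"` (default) or `"none"` for resubstitution.
#' @return A single AUC in `[0, 1]`.
#' @export
multiclass_auc <- function(st, features, groups = NULL, cv = c("loo", "none")) {
  cv <- match.arg(cv)
  stopifnot(inherits(st, "site_table"))
  samp <- st$samples
  if (!is.null(groups)) samp <- samp[samp$group %in% groups, , drop = FALSE]
  y <- factor(samp$group)
  if (nlevels(y) < 2L) stop2("AUC needs at least 2 groups")
  if (any(table(y) < 2L)) stop2("every group needs at least 2 samples")
  miss <- setdiff(features, st$sites$site_id)
  if (length(miss)) stop2("unknown features: ", paste(miss, collapse = ", "))
  x <- t(st$abundance[features, samp$sample_id, drop = FALSE])
  scores <- if (cv == "loo") loo_lda_scores(x, y) else
    lda_posterior(lda_fit(x, y), x)
  classes <- levels(y)
  if (length(classes) == 2L)
    return(rank_auc(scores[y == classes[2], classes[2]],
                    scores[y == classes[1], classes[2]]))
  pairs <- utils::combn(classes, 2)
  aucs <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    a_ij <- rank_auc(scores[y == i, i], scores[y == j, i])
    a_ji <- rank_auc(scores[y == j, j], scores[y == i, j])
    (a_ij + a_ji) / 2
  })
  mean(aucs)
}

# --- linear discriminant machinery -----------------------------------------
# Own generalized-eigen implementation: maximizes between/within scatter
# ratio, with a shrinkage fallback when the within-class scatter is
# singular (features close to sample count, or collinear panels).

lda_fit <- function(x, y, shrinkage = NULL) {
  y <- droplevels(factor(y))
  g <- nlevels(y)
  p <- ncol(x)
  n <- nrow(x)
  mu <- rowsum(x, y) / as.vector(table(y))
  grand <- colMeans(x)
  xc <- x - mu[y, , drop = FALSE]
  W <- crossprod(xc) / (n - g)              # pooled within-class covariance
  priors <- as.vector(table(y)) / n
  B <- crossprod(sqrt(as.vector(table(y))) * (mu - rep(grand, each = g)))
  if (is.null(shrinkage)) {
    # shrink when singular or badly conditioned
    ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
    shrinkage <- if (min(ev) <= max(ev) * 1e-8 || p >= n - g) 0.1 else 0
    if (shrinkage > 0)
      warning("singular within-class scatter: applying shrinkage",
              call. = FALSE)
  }
  if (shrinkage > 0)
    W <- (1 - shrinkage) * W + shrinkage * mean(diag(W)) * diag(p)
  # solve W^{-1/2} B W^{-1/2} symmetric eigenproblem
  eW <- eigen(W, symmetric = TRUE)
  Wih <- eW$vectors %*% diag(1 / sqrt(pmax(eW$values, 1e-12)), p) %*% t(eW$vectors)
  M <- Wih %*% B %*% Wih
  eM <- eigen(M, symmetric = TRUE)
  n_axes <- min(g - 1L, p)
  scal <- Wih %*% eM$vectors[, seq_len(n_axes), drop = FALSE]
  # sign convention: largest-|loading| positive per axis
  for (k in seq_len(ncol(scal))) {
    big <- which.max(abs(scal[, k]))
    if (scal[big, k] < 0) scal[, k] <- -scal[, k]
  }
  list(means = mu, scaling = scal, W = W, priors = priors,
       classes = levels(y), shrinkage = shrinkage)
}

lda_posterior <- function(fit, newx) {
  # Gaussian classes, shared covariance: linear discriminant scores
  z <- newx %*% fit$scaling
  mz <- fit$means %*% fit$scaling
  d <- sapply(seq_along(fit$classes), function(k) {
    dz <- sweep(z, 2, mz[k, ])
    -0.5 * rowSums(dz^2) + log(fit$priors[k])
  })
  if (is.null(dim(d))) d <- matrix(d, nrow = nrow(z))
  d <- d - apply(d, 1, max)
  post <- exp(d) / rowSums(exp(d))
  colnames(post) <- fit$classes
  post
}

#' Linear discriminant projection of samples
#'
#' Supervised projection of samples onto the (at most `groups - 1`, here
#' capped at 2) discriminant axes that maximize the between-group to
#' within-group scatter ratio, for visualising group separation. Axis
#' signs are fixed by forcing the largest-magnitude loading positive; a
#' shrinkage estimate of the within-class scatter is substituted (with a
#' warning) when it is singular.
#'
#' @param st a complete log2-scale `site_table`.
#' @param groups group labels to project (typically 3, e.g. CKD / low-grade
#'   / high-grade).
#' @param features optional `site_id` panel; default all sites.
#' @return List with `coordinates` (data frame `sample_id`, `group`,
#'   `LD1`, `LD2`, ...) and `scaling` (feature loadings).
#' @export
lda_project <- function(st, groups = NULL, features = NULL) {
  stopifnot(inherits(st, "site_table"))
  samp <- st$samples
  if (!is.null(groups)) samp <- samp[samp$group %in% groups, , drop = FALSE]
  y <- factor(samp$group)
  if (nlevels(y) < 2L) stop2("LDA needs at least 2 groups")
  feats <- features %||% st$sites$site_id
  x <- t(st$abundance[feats, samp$sample_id, drop = FALSE])
  fit <- lda_fit(x, y)
  n_axes <- min(2L, ncol(fit$scaling))
  z <- x %*% fit$scaling[, seq_len(n_axes), drop = FALSE]
  coords <- data.frame(sample_id = samp$sample_id, group = samp$group)
  for (k in seq_len(n_axes)) coords[[paste0("LD", k)]] <- z[, k]
  list(coordinates = coords,
       scaling = fit$scaling[, seq_len(n_axes), drop = FALSE],
       shrinkage = fit$shrinkage)
}
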