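# fixtures and independent oracles used across test files

# tiny hand-built precursor set
make_tiny_precursor_set <- function() {
  records <- data.frame(
    record_id = c("r1", "r2", "r3"),
    protein_accession = c("P1", "P1", "P2"),
    modified_sequence = c("AAS[+80]K", "LLS[+80]R", "TTS[+80]T[+80]K"),
    charge = c(2L, 2L, 3L))
  sites <- data.frame(
    record_id = c("r1", "r2", "r3", "r3"),
    position = c(5L, 5L, 5L, 9L),
    residue = c("S", "S", "S", "T"),
    localization_probability = c(0.99, 0.80, 0.95, 0.90))
  abundance <- matrix(c(100, 200,
                        50, 60,
                        80, NA),
                      nrow = 3, byrow = TRUE,
                      dimnames = list(c("r1", "r2", "r3"), c("s1", "s2")))
  samples <- data.frame(sample_id = c("s1", "s2"), group = c("g1", "g1"))
  precursor_set(records, sites, abundance, samples)
}

# brute-force rollup oracle: double loop over (record, site) pairs
rollup_oracle <- function(ps) {
  s <- ps$sites
  prot <- ps$records$protein_accession[match(s$record_id, ps$records$record_id)]
  key <- paste0(prot, "-", s$residue, s$position)
  ukey <- unique(key)
  out <- matrix(NA_real_, nrow = length(ukey), ncol = ncol(ps$abundance),
                dimnames = list(ukey, colnames(ps$abundance)))
  for (i in seq_len(nrow(s))) {
    row <- ps$abundance[as.character(s$record_id[i]), ]
    k <- key[i]
    for (j in seq_along(row)) {
      if (!is.na(row[j]))
        out[k, j] <- if (is.na(out[k, j])) row[j] else out[k, j] + row[j]
    }
  }
  out
}

# nonnegative least squares by projected quasi-Newton, independent of pracma
nnls_oracle <- function(A, b) {
  f <- function(x) sum((A %*% x - b)^2)
  g <- function(x) as.vector(2 * crossprod(A, A %*% x - b))
  res <- stats::optim(rep(0, ncol(A)), f, g, method = "L-BFGS-B",
                      lower = 0, control = list(factr = 1e1, maxit = 2000))
  res$par
}

# AUC by brute-force count of concordant pairs
pair_count_auc <- function(score_pos, score_neg) {
  tot <- 0
  for (p in score_pos) for (n in score_neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(score_pos) * length(score_neg))
}

# small complete site table with given group matrix (sites x samples)
make_site_table <- function(mat, groups, scale = "log2") {
  ns <- nrow(mat)
  sites <- data.frame(site_id = paste0("P", seq_len(ns), "-S", seq_len(ns)),
                      protein_accession = paste0("P", seq_len(ns)),
                      residue = "S", position = seq_len(ns))
  rownames(mat) <- sites$site_id
  samples <- data.frame(sample_id = paste0("x", seq_len(ncol(mat))),
                        group = groups)
  colnames(mat) <- samples$sample_id
  site_table(mat, sites, samples, scale = scale)
}
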