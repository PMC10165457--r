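#' Construct a precursor-level quantification set
#'
#' In-memory form of a search-software precursor export for
#' phosphoproteomics: one record per modified peptide precursor, each with
#' one or more phosphosite assignments (protein position, residue,
#' localization probability) and a raw intensity per sample. Zero
#' intensities are treated as missing, since exports use blanks and zeros
#' interchangeably.
#'
#' @param records data frame, one row per precursor: `record_id`,
#'   `protein_accession`, `modified_sequence`, `charge`.
#' @param sites data frame, one row per (record, site): `record_id`,
#'   `position` (1-based protein coordinate), `residue` (S/T/Y),
#'   `localization_probability` in `[0, 1]`.
#' @param abundance numeric matrix, rows named by `record_id`, columns by
#'   sample id; nonnegative raw intensities, `NA` for missing.
#' @param samples data frame with `sample_id` and `group`.
#' @return A `precursor_set` object.
#' @export
precursor_set <- function(records, sites, abundance, samples) {
  stopifnot(is.data.frame(records), is.data.frame(sites),
            is.matrix(abundance), is.data.frame(samples))
  if (anyDuplicated(records$record_id))
    stop2("duplicate record_id in 'records'")
  if (!all(sites$record_id %in% records$record_id))
    stop2("'sites' refers to unknown record_id")
  if (!all(sites$residue %in% c("S", "T", "Y")))
    stop2("site residues must be S, T or Y")
  if (any(sites$position < 1))
    stop2("site positions are 1-based and must be >= 1")
  p <- sites$localization_probability
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop2("localization probabilities must lie in [0, 1]")
  if (!identical(rownames(abundance) %||% character(0),
                 as.character(records$record_id)))
    stop2("abundance rownames must equal records$record_id")
  if (!identical(colnames(abundance) %||% character(0),
                 as.character(samples$sample_id)))
    stop2("abundance colnames must equal samples$sample_id")
  if (any(abundance < 0, na.rm = TRUE))
    stop2("abundances must be nonnegative")
  abundance[abundance == 0] <- NA_real_  # zeros are missing
  structure(list(records = records, sites = sites,
                 abundance = abundance, samples = samples),
            class = "precursor_set")
}

#' @export
print.precursor_set <- function(x, ...) {
  cat(sprintf("precursor_set: %d precursors, %d site assignments, %d samples\n",
              nrow(x$records), nrow(x$sites), nrow(x$samples)))
  invisible(x)
}

#' Filter phosphosite assignments to class-1 localization
#'
#' Retains, per precursor record, only the site assignments whose
#' localization probability meets the class-1 cutoff (inclusive); records
#' left with no confidently localized site are dropped. The conventional
#' cutoff is 0.75 for library-based DIA; library-free (direct) DIA
#' requires 0.99 for comparable error rates.
#'
#' @param ps a `precursor_set`.
#' @param cutoff probability cutoff in `(0, 1]`; default 0.75.
#' @return A filtered `precursor_set`.
#' @export
class1_filter <- function(ps, cutoff = 0.75) {
  stopifnot(inherits(ps, "precursor_set"))
  assert_number(cutoff, "cutoff")
  if (cutoff <= 0 || cutoff > 1) stop2("'cutoff' must lie in (0, 1]")
  keep_sites <- ps$sites[ps$sites$localization_probability >= cutoff, , drop = FALSE]
  keep_rec <- ps$records$record_id %in% keep_sites$record_id
  structure(list(records = ps$records[keep_rec, , drop = FALSE],
                 sites = keep_sites,
                 abundance = ps$abundance[keep_rec, , drop = FALSE],
                 samples = ps$samples),
            class = "precursor_set")
}

#' Roll precursor abundances up to phosphosite level
#'
#' The abundance of a phosphosite in a sample is the sum of the abundances
#' of all precursors containing that site; a multiply phosphorylated
#' precursor contributes its full abundance to each of its retained sites.
#' A site-sample cell is missing iff every contributing precursor is
#' missing there. Summing charge states of the same modified peptide first
#' would give identical totals, so no explicit grouping step is needed.
#'
#' @param ps a class-1-filtered `precursor_set`.
#' @return A [site_table()] on the raw intensity scale, with per-site
#'   contributing-precursor counts in `sites$n_precursors`.
#' @export
collapse_to_sites <- function(ps) {
  stopifnot(inherits(ps, "precursor_set"))
  if (nrow(ps$sites) == 0L) stop2("no site assignments to collapse")
  s <- ps$sites
  s$protein_accession <-
    ps$records$protein_accession[match(s$record_id, ps$records$record_id)]
  keypos <- paste(s$protein_accession, s$position)
  res_by_pos <- tapply(s$residue, keypos, function(r) length(unique(r)))
  if (any(res_by_pos > 1)) {
    bad <- names(res_by_pos)[res_by_pos > 1]
    stop2("conflicting residue letters at accession/position: ",
          paste(bad, collapse = "; "))
  }
  key <- paste0(s$protein_accession, "-", s$residue, s$position)
  ukey <- unique(key)
  ridx <- match(s$record_id, rownames(ps$abundance))
  n_samp <- ncol(ps$abundance)
  abn <- matrix(NA_real_, nrow = length(ukey), ncol = n_samp,
                dimnames = list(ukey, colnames(ps$abundance)))
  n_prec <- integer(length(ukey))
  for (i in seq_along(ukey)) {
    rows <- ridx[key == ukey[i]]
    block <- ps$abundance[rows, , drop = FALSE]
    any_obs <- colSums(!is.na(block)) > 0
    v <- colSums(block, na.rm = TRUE)
    v[!any_obs] <- NA_real_
    abn[i, ] <- v
    n_prec[i] <- length(rows)
  }
  first <- match(ukey, key)
  sites <- data.frame(site_id = ukey,
                      protein_accession = s$protein_accession[first],
                      residue = s$residue[first],
                      position = s$position[first],
                      n_precursors = n_prec)
  site_table(abn, sites, ps$samples, scale = "raw")
}

#' Residue composition of a site table
#'
#' @param st a `site_table`.
#' @return Named numeric vector of percentages for S, T and Y (sums to 100).
#' @export
residue_distribution <- function(st) {
  stopifnot(inherits(st, "site_table"))
  if (nrow(st$sites) == 0L) stop2("empty site table")
  tab <- table(factor(st$sites$residue, levels = c("S", "T", "Y")))
  pct <- 100 * as.vector(tab) / sum(tab)
  names(pct) <- c("S", "T", "Y")
  pct
}

#' Replicate coefficient of variation
#'
#' CV% per feature over replicate columns of a raw-scale abundance matrix:
#' `100 * sd / mean` of the non-missing values. Rows with fewer than two
#' observed replicates return `NA`; a zero mean returns `NA` with a warning.
#'
#' @param x numeric matrix (features x replicates), raw scale.
#' @return Numeric vector of CV percentages, one per row.
#' @examples
#' replicate_cv(rbind(c(90, 100, 110)))  # 10
#' @export
replicate_cv <- function(x) {
  stopifnot(is.matrix(x))
  apply(x, 1, function(r) {
    v <- r[!is.na(r)]
    if (length(v) < 2L) return(NA_real_)
    m <- mean(v)
    if (m == 0) {
      warning("zero mean in replicate_cv; returning NA", call. = FALSE)
      return(NA_real_)
    }
    100 * stats::sd(v) / m
  })
}

#' Library fragment-ion filter
#'
#' Applies the fragment-ion quality rules used when building a DIA spectral
#' library: m/z within `[300, 1800]`, relative intensity at least 5%, at
#' least three amino-acid residues; neutral-loss fragments are retained.
#' The surviving ions are then truncated to the 15 most intense.
#'
#' @param ions data frame with columns `mz`, `relative_intensity` (in
#'   `[0, 1]`), `residue_count`, `neutral_loss` (logical).
#' @param min_mz,max_mz,min_rel_intensity,min_residues,top_n filter
#'   parameters with library-building defaults.
#' @return The filtered data frame, ordered by decreasing intensity.
#' @export
filter_fragment_ions <- function(ions, min_mz = 300, max_mz = 1800,
                                 min_rel_intensity = 0.05, min_residues = 3,
                                 top_n = 15) {
  stopifnot(is.data.frame(ions),
            all(c("mz", "relative_intensity", "residue_count") %in% names(ions)))
  keep <- ions$mz >= min_mz & ions$mz <= max_mz &
    ions$relative_intensity >= min_rel_intensity &
    ions$residue_count >= min_residues
  out <- ions[keep, , drop = FALSE]
  out <- out[order(-out$relative_intensity), , drop = FALSE]
  utils::head(out, top_n)
}
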