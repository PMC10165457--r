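#' Phosphosite x sample abundance table
#'
#' The central container of the quantitative pipeline: a numeric matrix of
#' site abundances with site annotation, the sample sheet with group
#' labels, and a record of the intensity scale (`"raw"` or `"log2"`).
#'
#' @param abundance numeric matrix, sites x samples, rownames = site ids.
#' @param sites data frame: `site_id`, `protein_accession`, `residue`,
#'   `position`, optionally `n_precursors`.
#' @param samples data frame: `sample_id`, `group`.
#' @param scale `"raw"` or `"log2"`.
#' @return A `site_table` object.
#' @export
site_table <- function(abundance, sites, samples, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(abundance), is.data.frame(sites), is.data.frame(samples))
  if (anyDuplicated(sites$site_id)) stop2("duplicate site_id in 'sites'")
  if (!identical(rownames(abundance) %||% character(0),
                 as.character(sites$site_id)))
    stop2("abundance rownames must equal sites$site_id")
  if (!identical(colnames(abundance) %||% character(0),
                 as.character(samples$sample_id)))
    stop2("abundance colnames must equal samples$sample_id")
  structure(list(abundance = abundance, sites = sites,
                 samples = samples, scale = scale),
            class = "site_table")
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("site_table: %d phosphosites x %d samples (%s scale)\n",
              nrow(x$abundance), ncol(x$abundance), x$scale))
  if (length(unique(x$samples$group)) > 1L) {
    tab <- table(x$samples$group)
    cat("  groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# replace the abundance matrix, keeping annotation in sync
set_abundance <- function(st, abn, scale = st$scale) {
  keep <- rownames(abn)
  site_table(abn, st$sites[match(keep, st$sites$site_id), , drop = FALSE],
             st$samples[match(colnames(abn), st$samples$sample_id), , drop = FALSE],
             scale = scale)
}

# subset samples (columns) of a site_table
subset_samples <- function(st, sample_ids) {
  abn <- st$abundance[, sample_ids, drop = FALSE]
  site_table(abn, st$sites,
             st$samples[match(sample_ids, st$samples$sample_id), , drop = FALSE],
             scale = st$scale)
}
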