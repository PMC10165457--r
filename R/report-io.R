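# long-format precursor report dialect: one row per (precursor, sample);
# multi-site fields packed with ";"
REPORT_COLUMNS <- c("protein_accession", "modified_sequence", "charge",
                    "site_positions", "site_residues",
                    "localization_probabilities", "sample_id", "intensity")

#' Write a precursor set as a long-format delimited report
#'
#' One row per (precursor, sample) with site positions, residues and
#' localization probabilities packed into semicolon-separated fields --
#' the layout of search-software precursor exports. Numbers are written at
#' full precision so a round trip is exact.
#'
#' @param ps a `precursor_set`.
#' @param path output TSV path.
#' @param design_path optional path for the sample sheet
#'   (`sample_id`, `group`).
#' @return `path`, invisibly.
#' @export
write_precursor_report <- function(ps, path, design_path = NULL) {
  stopifnot(inherits(ps, "precursor_set"))
  fmt <- function(x) sprintf("%.17g", x)
  by_rec <- split(ps$sites, ps$sites$record_id)
  rec <- ps$records
  packed <- lapply(by_rec, function(s) list(
    pos = paste(s$position, collapse = ";"),
    res = paste(s$residue, collapse = ";"),
    loc = paste(fmt(s$localization_probability), collapse = ";")))
  long <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i) {
    id <- rec$record_id[i]
    pk <- packed[[as.character(id)]]
    ab <- ps$abundance[i, ]
    obs <- !is.na(ab)
    if (!any(obs)) return(NULL)
    data.frame(protein_accession = rec$protein_accession[i],
               modified_sequence = rec$modified_sequence[i],
               charge = rec$charge[i],
               site_positions = pk$pos, site_residues = pk$res,
               localization_probabilities = pk$loc,
               sample_id = names(ab)[obs], intensity = fmt(ab[obs]))
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(design_path))
    utils::write.table(ps$samples, design_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read a long-format precursor report
#'
#' Parses the delimited dialect written by [write_precursor_report()].
#' Rows violating the type invariants (probabilities outside `[0, 1]`,
#' nonpositive positions, residues other than S/T/Y, negative intensities)
#' are routed to an error report rather than aborting the run.
#'
#' @param path report TSV path.
#' @param design either a sample-sheet TSV path or a data frame
#'   (`sample_id`, `group`); if `NULL`, samples get group `"unknown"`.
#' @return List with `records` (a [precursor_set()]) and `errors` (data
#'   frame of rejected rows with a `reason` column).
#' @export
read_precursor_report <- function(path, design = NULL) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  absent <- setdiff(REPORT_COLUMNS, header)
  if (length(absent))
    stop2("report lacks mandatory columns: ", paste(absent, collapse = ", "))
  # packed multi-site fields must stay character to keep full precision
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE,
                           colClasses = c(site_positions = "character",
                                          site_residues = "character",
                                          localization_probabilities = "character"))
  if (nrow(raw) == 0L)
    warning("empty report (header only)", call. = FALSE)

  split_num <- function(s) as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  split_chr <- function(s) strsplit(s, ";", fixed = TRUE)[[1]]
  bad <- logical(nrow(raw)); reason <- character(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    loc <- split_num(as.character(raw$localization_probabilities[i]))
    pos <- split_num(as.character(raw$site_positions[i]))
    res <- split_chr(as.character(raw$site_residues[i]))
    r <- NULL
    if (anyNA(loc) || any(loc < 0 | loc > 1)) r <- "localization probability outside [0, 1]"
    else if (anyNA(pos) || any(pos < 1)) r <- "site position < 1"
    else if (!all(res %in% c("S", "T", "Y"))) r <- "residue not S/T/Y"
    else if (length(unique(c(length(loc), length(pos), length(res)))) != 1L)
      r <- "ragged site fields"
    else if (is.na(raw$intensity[i]) || as.numeric(raw$intensity[i]) < 0)
      r <- "negative or missing intensity"
    if (!is.null(r)) { bad[i] <- TRUE; reason[i] <- r }
  }
  errors <- cbind(raw[bad, , drop = FALSE], reason = reason[bad])
  ok <- raw[!bad, , drop = FALSE]

  if (is.character(design)) design <- utils::read.delim(design, sep = "\t",
                                                        stringsAsFactors = FALSE)
  sample_ids <- unique(ok$sample_id)
  if (is.null(design))
    design <- data.frame(sample_id = sample_ids,
                         group = rep("unknown", length(sample_ids)))
  design$sample_id <- as.character(design$sample_id)
  sample_ids <- design$sample_id

  rec_key <- paste(ok$protein_accession, ok$modified_sequence, ok$charge,
                   ok$site_positions, sep = "\r")
  ukey <- unique(rec_key)
  record_id <- sprintf("PRE%05d", seq_along(ukey))
  first <- match(ukey, rec_key)
  records <- data.frame(record_id = record_id,
                        protein_accession = ok$protein_accession[first],
                        modified_sequence = ok$modified_sequence[first],
                        charge = ok$charge[first])
  empty_sites <- data.frame(record_id = character(0), position = numeric(0),
                            residue = character(0),
                            localization_probability = numeric(0))
  sites <- do.call(rbind, lapply(seq_along(ukey), function(k) {
    i <- first[k]
    data.frame(record_id = record_id[k],
               position = split_num(as.character(ok$site_positions[i])),
               residue = split_chr(as.character(ok$site_residues[i])),
               localization_probability =
                 split_num(as.character(ok$localization_probabilities[i])))
  })) %||% empty_sites
  abn <- matrix(NA_real_, nrow = length(ukey), ncol = length(sample_ids),
                dimnames = list(record_id, sample_ids))
  ridx <- match(rec_key, ukey)
  cidx <- match(ok$sample_id, sample_ids)
  abn[cbind(ridx, cidx)] <- as.numeric(ok$intensity)
  list(records = precursor_set(records, sites, abn, design), errors = errors)
}

#' Write a site table as TSV with a sample-group header block
#'
#' The first lines are `#group<TAB>sample<TAB>label` comments recording the
#' design, followed by a site x sample matrix with annotation columns.
#'
#' @param st a `site_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(st, path) {
  stopifnot(inherits(st, "site_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#scale\t%s", st$scale), con)
  writeLines(sprintf("#group\t%s\t%s", st$samples$sample_id, st$samples$group), con)
  df <- cbind(st$sites[, c("site_id", "protein_accession", "residue", "position")],
              as.data.frame(apply(st$abundance, 2, sprintf, fmt = "%.17g")))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site table written by [write_site_table()]
#'
#' @param path input path.
#' @return A `site_table`.
#' @export
read_site_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  scale <- sub("^#scale\t", "", grep("^#scale\t", hdr, value = TRUE))
  gl <- strsplit(grep("^#group\t", hdr, value = TRUE), "\t", fixed = TRUE)
  samples <- data.frame(sample_id = vapply(gl, `[`, "", 2),
                        group = vapply(gl, `[`, "", 3))
  body <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
  ann <- c("site_id", "protein_accession", "residue", "position")
  abn <- as.matrix(body[, setdiff(names(body), ann), drop = FALSE])
  abn <- abn[, samples$sample_id, drop = FALSE]
  storage.mode(abn) <- "double"
  rownames(abn) <- body$site_id
  site_table(abn, body[, ann], samples, scale = scale)
}
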