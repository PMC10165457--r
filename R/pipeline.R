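#' Configuration of a full differential run
#'
#' Collects stage parameters, comparisons and the master seed for
#' [run_pipeline()]. Every stochastic stage derives its own substream from
#' the master seed via [stage_seed()], so a rerun with an identical
#' configuration reproduces the statistical outputs byte for byte.
#'
#' @param sim a [simulation_config()] used when no report is supplied.
#' @param report_path,design_path optional precursor report + sample sheet
#'   to analyse instead of simulating.
#' @param class1_cutoff localization cutoff, default 0.75.
#' @param qc_floor intensity floor, default 30.
#' @param normality_alpha per-sample normality exclusion level, default 0.01.
#' @param completeness group completeness fraction, default 0.70 (strict).
#' @param downshift_sd,width_sd imputation parameters, defaults 1.8 / 0.3.
#' @param p_cutoff,lfc_cutoff volcano cutoffs, defaults 0.05 / 0.5.
#' @param comparisons list of `c(group_a, group_b)` pairs; default the
#'   disease-vs-control contrasts of the four-group design.
#' @param top_k random-forest features to keep per comparison, default 15.
#' @param seed master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = simulation_config(),
                       report_path = NULL, design_path = NULL,
                       class1_cutoff = 0.75, qc_floor = 30,
                       normality_alpha = 0.01, completeness = 0.70,
                       downshift_sd = 1.8, width_sd = 0.3,
                       p_cutoff = 0.05, lfc_cutoff = 0.5,
                       comparisons = list(c("CKD", "HC"),
                                          c("low_grade", "HC"),
                                          c("high_grade", "HC"),
                                          c("low_grade", "CKD"),
                                          c("high_grade", "CKD")),
                       top_k = 15, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  sprintf("%08x", stage_seed(0L, s))
}

#' Run the full phosphosite differential pipeline
#'
#' Executes, in order: simulate (or read) the precursor report, class-1
#' localization filter, rollup to sites, QC floor, log2 transform,
#' per-sample normality gate, then per comparison the completeness filter,
#' downshifted imputation, median normalization and Welch volcano
#' classification; finally random-forest ranking of the volcano-up sites
#' and a multiclass AUC per comparison. Artifacts are written as TSV files
#' stamped with the configuration hash and seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @return Invisible list: `site_table`, per-comparison `volcano` results,
#'   `rankings`, `auc`, `normality_report` and a `summary` of counts
#'   surviving each stage.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stamp <- sprintf("# config %s seed %d", config_hash(config), config$seed)

  if (!is.null(config$report_path)) {
    rd <- read_precursor_report(config$report_path, config$design_path)
    ps <- rd$records
  } else {
    cfg <- config$sim
    cfg$seed <- stage_seed(config$seed, "simulate")
    ps <- simulate_report(cfg)$records
  }
  n_records_in <- nrow(ps$records)

  groups_present <- unique(ps$samples$group)
  for (cmp in config$comparisons)
    if (!all(cmp %in% groups_present))
      stop2("unknown comparison group: ",
            paste(setdiff(cmp, groups_present), collapse = ", "))

  ps <- class1_filter(ps, config$class1_cutoff)
  st <- collapse_to_sites(ps)
  n_sites <- nrow(st$sites)
  st <- qc_floor(st, config$qc_floor)
  st <- log2_transform(st)
  gate <- sample_normality_gate(st, alpha = config$normality_alpha)
  st <- gate$table

  volcano <- list(); rankings <- list(); auc <- list()
  for (cmp in config$comparisons) {
    key <- paste(cmp, collapse = "_vs_")
    sub <- group_completeness_filter(st, cmp[1], cmp[2], config$completeness)
    sub <- impute_downshift(sub, config$downshift_sd, config$width_sd,
                            seed = stage_seed(config$seed, paste0("impute:", key)))
    sub <- median_normalize(sub)
    res <- welch_volcano(sub, cmp[1], cmp[2],
                         p_cutoff = config$p_cutoff,
                         lfc_cutoff = config$lfc_cutoff)
    volcano[[key]] <- res
    up <- res$site_id[res$volcano_class == "up"]
    if (length(up) >= 2) {
      cand <- set_abundance(sub, sub$abundance[up, , drop = FALSE])
      rk <- rf_importance(cand, top_k = config$top_k,
                          seed = stage_seed(config$seed, paste0("rf:", key)))
      rankings[[key]] <- rk
      auc[[key]] <- multiclass_auc(sub, rk$site_id, groups = cmp)
    }
    if (!is.null(out_dir)) {
      f <- file.path(out_dir, paste0("volcano_", key, ".tsv"))
      writeLines(stamp, f)
      suppressWarnings(utils::write.table(res, f, sep = "\t", quote = FALSE,
                                          row.names = FALSE, append = TRUE))
      if (!is.null(rankings[[key]])) {
        f2 <- file.path(out_dir, paste0("ranking_", key, ".tsv"))
        writeLines(stamp, f2)
        suppressWarnings(utils::write.table(rankings[[key]], f2, sep = "\t",
                                            quote = FALSE, row.names = FALSE,
                                            append = TRUE))
      }
    }
  }
  summary <- list(
    n_records_in = n_records_in,
    n_records_class1 = nrow(ps$records),
    n_sites = n_sites,
    n_samples_kept = nrow(st$samples),
    n_samples_excluded = sum(gate$report$status == "excluded"),
    n_up = vapply(volcano, function(v) sum(v$volcano_class == "up"), 0L),
    n_down = vapply(volcano, function(v) sum(v$volcano_class == "down"), 0L))
  if (!is.null(out_dir)) {
    f <- file.path(out_dir, "run_summary.tsv")
    writeLines(c(stamp, sprintf("%s\t%s", names(unlist(summary)),
                                unlist(summary))), f)
  }
  invisible(list(site_table = st, volcano = volcano, rankings = rankings,
                 auc = auc, normality_report = gate$report, summary = summary))
}
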