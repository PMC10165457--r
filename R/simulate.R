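#' Configuration for the synthetic phosphoproteome report generator
#'
#' Defaults emulate the structure of a urinary extracellular-vesicle
#' phosphoproteomics study: 2584 phosphosites quantified over four patient
#' groups (healthy control, chronic kidney disease, clear cell low-grade
#' and high-grade renal cell carcinoma) of 15 samples each, a 79/17/4
#' pS/pT/pY residue mix, log-normal raw intensities whose lower tail falls
#' below the QC floor of 30, intensity-dependent (left-censored)
#' missingness, localization probabilities from a well-localized/diffuse
#' mixture straddling the class-1 cutoff, and 1-3 precursors per site so
#' that site rollup is exercised. Each disease group carries its own set
#' of planted marker sites with a log2 effect.
#'
#' @param n_sites number of phosphosites, default 2584.
#' @param n_samples_per_group samples per group, default 15.
#' @param groups group labels, first one is the unaffected baseline.
#' @param residue_probs S/T/Y probabilities, default `c(0.79, 0.17, 0.04)`.
#' @param base_log2_mean,between_site_sd mean and SD of per-site baseline
#'   log2 abundance (defaults 10 and 2.5, placing roughly the lower 2-3%
#'   of raw intensities under the floor of 30).
#' @param within_group_sd per-cell log2 noise SD, default 0.5.
#' @param n_markers_per_group planted marker sites per non-baseline group,
#'   default 20.
#' @param effect_size planted marker effect in log2 units, default 1.5.
#' @param miss_midpoint,miss_steepness logistic missingness in latent log2
#'   intensity: `P(missing) = plogis(-(x - midpoint) * steepness)`
#'   (defaults 6 and 1.2); `mcar_rate` adds that much missingness
#'   completely at random (default 0, for null calibration).
#' @param loc_well_fraction fraction of precursors with well-localized
#'   sites, default 0.8; their probabilities come from Beta(40, 1.5), the
#'   remainder from the diffuse Beta(2, 2).
#' @param precursor_geom_p geometric parameter of the 1-3 truncated
#'   precursors-per-site distribution, default 0.6.
#' @param seed master seed.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_sites = 2584, n_samples_per_group = 15,
                              groups = c("HC", "CKD", "low_grade", "high_grade"),
                              residue_probs = c(S = 0.79, T = 0.17, Y = 0.04),
                              base_log2_mean = 10, between_site_sd = 2.5,
                              within_group_sd = 0.5,
                              n_markers_per_group = 20, effect_size = 1.5,
                              miss_midpoint = 6, miss_steepness = 1.2,
                              mcar_rate = 0,
                              loc_well_fraction = 0.8,
                              precursor_geom_p = 0.6,
                              seed = 1L) {
  if (n_sites < 1 || n_samples_per_group < 1)
    stop2("degenerate configuration: need at least 1 site and 1 sample per group")
  if (abs(sum(residue_probs) - 1) > 1e-8)
    stop2("'residue_probs' must sum to 1")
  if (between_site_sd <= 0 || within_group_sd < 0)
    stop2("spread parameters must be positive")
  if (!is.finite(effect_size)) stop2("'effect_size' must be finite")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a precursor-level phosphoproteomics report with ground truth
#'
#' Latent log2 site abundance = site baseline + planted group effect
#' (marker sites only) + Gaussian noise; raw intensity is its
#' exponentiation, split across 1-3 precursors with fixed per-precursor
#' weights (so group contrasts survive the split). Cells are censored by
#' an intensity-dependent logistic missingness model; each precursor-site
#' gets a localization probability from the two-component mixture.
#'
#' @param config a [simulation_config()].
#' @return List with `records` (a [precursor_set()]) and `truth`: per-site
#'   true group means (`group_means`), `marker_sites` (list per group),
#'   `missing` indicator matrix at the precursor level, and the config.
#' @export
simulate_report <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(stage_seed(cf$seed, "simulate_report"))
  n_groups <- length(cf$groups)
  n_samp <- n_groups * cf$n_samples_per_group
  samples <- data.frame(
    sample_id = sprintf("%s_%02d", rep(cf$groups, each = cf$n_samples_per_group),
                        rep(seq_len(cf$n_samples_per_group), n_groups)),
    group = rep(cf$groups, each = cf$n_samples_per_group))

  residue <- sample(names(cf$residue_probs), cf$n_sites, replace = TRUE,
                    prob = cf$residue_probs)
  protein <- sprintf("PROT%04d", sample.int(max(1L, ceiling(cf$n_sites / 3)),
                                            cf$n_sites, replace = TRUE))
  position <- integer(cf$n_sites)
  for (pr in unique(protein)) {
    idx <- which(protein == pr)
    position[idx] <- sort(sample.int(5000L, length(idx)))
  }
  site_id <- paste0(protein, "-", residue, position)

  baseline <- stats::rnorm(cf$n_sites, cf$base_log2_mean, cf$between_site_sd)
  effects <- matrix(0, nrow = cf$n_sites, ncol = n_groups,
                    dimnames = list(site_id, cf$groups))
  marker_sites <- list()
  if (cf$n_markers_per_group > 0 && n_groups > 1) {
    pool <- sample.int(cf$n_sites)  # disjoint marker sets across groups
    for (k in seq_along(cf$groups[-1])) {
      grp <- cf$groups[-1][k]
      take <- pool[seq.int((k - 1) * cf$n_markers_per_group + 1,
                           k * cf$n_markers_per_group)]
      effects[take, grp] <- cf$effect_size
      marker_sites[[grp]] <- site_id[take]
    }
  }
  group_means <- baseline + effects  # n_sites x n_groups

  # latent per-cell log2 abundance at site level
  gidx <- match(samples$group, cf$groups)
  latent <- group_means[, gidx, drop = FALSE] +
    matrix(stats::rnorm(cf$n_sites * n_samp, 0, cf$within_group_sd),
           cf$n_sites, n_samp)
  colnames(latent) <- samples$sample_id

  # 1-3 precursors per site, truncated geometric
  pgeo <- cf$precursor_geom_p * (1 - cf$precursor_geom_p)^(0:2)
  n_prec <- sample(1:3, cf$n_sites, replace = TRUE, prob = pgeo / sum(pgeo))
  rec_site <- rep(seq_len(cf$n_sites), n_prec)
  n_rec <- length(rec_site)
  # fixed per-precursor split weights so relative group effects are exact
  w <- stats::rgamma(n_rec, shape = 3)
  w <- as.numeric(w / rep(tapply(w, rec_site, sum), n_prec))  # rec_site is sorted

  raw_site <- 2^latent
  raw <- raw_site[rec_site, , drop = FALSE] * w
  record_id <- sprintf("PRE%05d", seq_len(n_rec))
  rownames(raw) <- record_id

  # intensity-dependent left-censored missingness on precursor cells
  p_miss <- stats::plogis(-(log2(raw) - cf$miss_midpoint) * cf$miss_steepness)
  p_miss[is.nan(p_miss)] <- 0.5  # 0 * Inf at the exact midpoint of a sharp threshold
  miss <- matrix(stats::runif(length(raw)) < p_miss, nrow = n_rec)
  if (cf$mcar_rate > 0)
    miss <- miss | matrix(stats::runif(length(raw)) < cf$mcar_rate, nrow = n_rec)
  raw[miss] <- NA_real_
  dimnames(raw) <- list(record_id, samples$sample_id)

  # localization probabilities: well-localized vs diffuse mixture
  well <- stats::runif(n_rec) < cf$loc_well_fraction
  loc <- ifelse(well, stats::rbeta(n_rec, 40, 1.5), stats::rbeta(n_rec, 2, 2))

  # distinct peptidoforms (missed-cleavage / charge variants) per site
  variant <- stats::ave(rec_site, rec_site, FUN = seq_along)
  mod_seq <- sprintf("PEP%04d.%d[+79.966]", rec_site, variant)
  records <- data.frame(record_id = record_id,
                        protein_accession = protein[rec_site],
                        modified_sequence = mod_seq,
                        charge = sample(2:3, n_rec, replace = TRUE))
  sites <- data.frame(record_id = record_id,
                      position = position[rec_site],
                      residue = residue[rec_site],
                      localization_probability = loc)
  ps <- precursor_set(records, sites, raw, samples)
  truth <- list(site_id = site_id, group_means = group_means,
                marker_sites = marker_sites, missing = miss,
                latent_log2 = latent, config = cf)
  list(records = ps, truth = truth)
}

#' Simulate staggered scan cycles for demultiplexing tests
#'
#' Each scan of each cycle observes the summed intensity of the analytes
#' whose precursor m/z falls inside its isolation window, plus optional
#' Gaussian noise; ground truth records each analyte's effective
#' half-window.
#'
#' @param scheme a `window_scheme`.
#' @param analytes data frame: `precursor_mz`, `fragment_channel`,
#'   `intensity` (>= 0). All m/z must lie within the scheme span.
#' @param n_cycles number of duty cycles, default 3.
#' @param noise_sd additive Gaussian noise SD on each observation, default 0.
#' @param seed seed for the noise draws.
#' @return List with `cycles` (scan table for [demultiplex()]) and `truth`
#'   (analytes annotated with `effective_index`).
#' @export
simulate_scan_cycles <- function(scheme, analytes, n_cycles = 3,
                                 noise_sd = 0, seed = 1L) {
  stopifnot(inherits(scheme, "window_scheme"), is.data.frame(analytes))
  if (nrow(analytes) > 0) {
    if (any(analytes$intensity < 0)) stop2("analyte intensities must be >= 0")
    out_of_span <- analytes$precursor_mz < scheme$span_lower |
      analytes$precursor_mz >= scheme$span_upper
    if (any(out_of_span))
      stop2("analyte precursor m/z outside the scheme span")
  }
  set.seed(stage_seed(seed, "simulate_scan_cycles"))
  eff <- effective_windows(scheme)
  truth <- analytes
  truth$effective_index <- if (nrow(analytes)) {
    findInterval(analytes$precursor_mz, eff$lower)
  } else integer(0)

  grid <- rbind(cbind(scheme$phase_a, phase = "a"),
                cbind(scheme$phase_b, phase = "b"))
  channels <- unique(analytes$fragment_channel)
  if (length(channels) == 0L) channels <- "ch1"
  rows <- list()
  for (cy in seq_len(n_cycles)) {
    for (s in seq_len(nrow(grid))) {
      inside <- if (nrow(analytes)) {
        analytes$precursor_mz >= grid$lower[s] &
          analytes$precursor_mz < grid$upper[s]
      } else logical(0)
      for (ch in channels) {
        sel <- inside & analytes$fragment_channel == ch
        obs <- sum(analytes$intensity[sel])
        if (noise_sd > 0) obs <- max(0, obs + stats::rnorm(1, 0, noise_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          cycle = cy, phase = grid$phase[s],
          window_lower = grid$lower[s], window_upper = grid$upper[s],
          fragment_channel = ch, intensity = obs)
      }
    }
  }
  list(cycles = do.call(rbind, rows), truth = truth)
}
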