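#' Forbidden-zone parameters for phosphopeptide precursors
#'
#' Peptide precursor masses cluster by mass defect, leaving narrow m/z
#' bands -- "forbidden zones" -- in which no (phospho)peptide precursor can
#' occur. Placing isolation-window edges inside these bands avoids cutting
#' real precursors in half at the quadrupole edge. The zone positions are
#' linear in nominal mass; phospho-enrichment shifts the peptide mass-defect
#' cluster, which is absorbed into the additive constant.
#'
#' @param mz_increment m/z spacing per nominal-mass unit. The optimal value
#'   for tryptic phosphopeptides is 1.00045475 (the default).
#' @param mz_constant additive m/z offset of the zone for the phospho
#'   modification, default 0.18.
#' @return An object of class `fz_params`.
#' @examples
#' forbidden_zone_params()
#' @export
forbidden_zone_params <- function(mz_increment = 1.00045475, mz_constant = 0.18) {
  assert_number(mz_increment, "mz_increment")
  assert_number(mz_constant, "mz_constant")
  if (mz_increment <= 1.0 || mz_increment >= 1.001)
    stop2("'mz_increment' must lie in (1.0, 1.001)")
  if (mz_constant < 0 || mz_constant >= 1)
    stop2("'mz_constant' must lie in [0, 1)")
  structure(list(mz_increment = mz_increment, mz_constant = mz_constant),
            class = "fz_params")
}

#' @export
print.fz_params <- function(x, ...) {
  cat(sprintf("Forbidden-zone parameters: increment %.8f m/z per Da, constant %.4f m/z\n",
              x$mz_increment, x$mz_constant))
  invisible(x)
}

#' Forbidden-zone boundary for a nominal mass
#'
#' Computes the optimal window-edge m/z associated with an integer nominal
#' mass: `ceil(nominal_mass / mz_increment) * mz_increment + mz_constant`.
#' For nominal masses in the usual precursor range (below ~2200 Da) the
#' ceiling is the identity, so boundaries are exactly linear in nominal mass.
#'
#' @param nominal_mass integer nominal mass in Da (vectorised, >= 0).
#' @param params a [forbidden_zone_params()] object.
#' @return Boundary m/z value(s), double precision.
#' @examples
#' forbidden_zone_boundary(500)   # 500.407375
#' @export
forbidden_zone_boundary <- function(nominal_mass, params = forbidden_zone_params()) {
  stopifnot(inherits(params, "fz_params"))
  if (!is.numeric(nominal_mass) || any(is.na(nominal_mass)))
    stop2("'nominal_mass' must be numeric and non-missing")
  if (any(nominal_mass < 0))
    stop2("'nominal_mass' must be >= 0 (negative masses are meaningless)")
  if (any(nominal_mass != round(nominal_mass)))
    stop2("'nominal_mass' must be integer-valued Da")
  ceiling(nominal_mass / params$mz_increment) * params$mz_increment + params$mz_constant
}

#' Snap an m/z value to the nearest forbidden-zone boundary
#'
#' Returns the boundary `forbidden_zone_boundary(m)` minimising the distance
#' to `target` over integer nominal masses `m`; exact ties are broken toward
#' the lower boundary so snapping is deterministic.
#'
#' @param target m/z value(s) to snap, > 0.
#' @param params a [forbidden_zone_params()] object.
#' @return Snapped m/z value(s).
#' @examples
#' snap_to_forbidden_zone(500.40)  # 500.407375
#' @export
snap_to_forbidden_zone <- function(target, params = forbidden_zone_params()) {
  stopifnot(inherits(params, "fz_params"))
  if (!is.numeric(target) || any(is.na(target)) || any(target <= 0))
    stop2("'target' must be positive m/z")
  vapply(target, function(tg) {
    m0 <- floor((tg - params$mz_constant) / params$mz_increment)
    cand <- pmax(0, m0 + (-1:2))
    b <- ceiling(cand / params$mz_increment) * params$mz_increment + params$mz_constant
    d <- abs(b - tg)
    # which.min returns the first (lower-boundary) index on exact ties
    b[which.min(d)]
  }, numeric(1))
}
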