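#' Build a staggered DIA isolation-window scheme
#'
#' Lays two interleaved grids of contiguous isolation windows over the
#' precursor span: phase A starts at `span_lower`; phase B is the same grid
#' shifted up by half a window width, so that computational demultiplexing
#' can later resolve signal to half-width "effective" windows. Windows are
#' half-open `[lower, upper)` so a shared edge belongs to exactly one
#' window. The window count per phase uses ceiling division, so the last
#' window may overhang `span_upper` (this is what yields the instrument
#' loop count of 88 for a 700 m/z span at 8 m/z windows). When `align` is
#' set, every window edge is snapped to its nearest phosphopeptide
#' forbidden-zone boundary; shared edges snap identically, so contiguity
#' within each phase is preserved.
#'
#' @param span_lower,span_upper precursor span in m/z, `span_upper > span_lower`.
#' @param window_width nominal isolation-window width in m/z.
#' @param align logical; snap all window edges to forbidden zones.
#' @param params a [forbidden_zone_params()] object used when `align = TRUE`.
#' @return A `window_scheme` object: list with `span_lower`, `span_upper`,
#'   `window_width`, data frames `phase_a` / `phase_b` (columns `lower`,
#'   `upper`) in acquisition order, and `aligned_to_forbidden_zones`.
#' @examples
#' sch <- build_staggered_scheme(400, 1100, 8)
#' nrow(sch$phase_a)  # 88
#' @export
build_staggered_scheme <- function(span_lower, span_upper, window_width,
                                   align = FALSE,
                                   params = forbidden_zone_params()) {
  assert_number(span_lower, "span_lower", lower = 0)
  assert_number(span_upper, "span_upper")
  assert_number(window_width, "window_width")
  stopifnot(is_flag(align))
  if (span_upper <= span_lower) stop2("'span_upper' must exceed 'span_lower'")
  if (window_width <= 0) stop2("'window_width' must be positive")
  span <- span_upper - span_lower
  if (window_width >= span) {
    warning("window_width >= span: scheme degenerates to one window per phase",
            call. = FALSE)
    n <- 1L
  } else {
    n <- as.integer(ceiling(span / window_width - 1e-9))
  }
  lower_a <- span_lower + window_width * (seq_len(n) - 1L)
  phase_a <- data.frame(lower = lower_a, upper = lower_a + window_width)
  phase_b <- data.frame(lower = phase_a$lower + window_width / 2,
                        upper = phase_a$upper + window_width / 2)
  if (align) {
    snap_edges <- function(df) {
      lo <- snap_to_forbidden_zone(df$lower, params)
      # contiguity: each window's upper edge is the next window's lower edge
      up <- c(lo[-1], snap_to_forbidden_zone(df$upper[nrow(df)], params))
      data.frame(lower = lo, upper = up)
    }
    phase_a <- snap_edges(phase_a)
    phase_b <- snap_edges(phase_b)
  }
  structure(list(span_lower = span_lower, span_upper = span_upper,
                 window_width = window_width,
                 phase_a = phase_a, phase_b = phase_b,
                 aligned_to_forbidden_zones = align),
            class = "window_scheme")
}

#' @export
print.window_scheme <- function(x, ...) {
  cat(sprintf(
    "Staggered DIA window scheme: span %g-%g m/z, %g m/z windows, %d per phase%s\n",
    x$span_lower, x$span_upper, x$window_width, nrow(x$phase_a),
    if (x$aligned_to_forbidden_zones) ", edges on forbidden zones" else ""))
  invisible(x)
}

#' Summarise a window scheme
#'
#' Reports the per-phase window count, total span and the effective window
#' width after staggered demultiplexing, which is exactly half the nominal
#' width (a 4 m/z staggered scheme deconvolves to 2 m/z effective windows).
#'
#' @param scheme a `window_scheme`.
#' @return A list with `n_windows_per_phase`, `span_lower`, `span_upper`,
#'   `window_width`, `effective_width`, `aligned_to_forbidden_zones`.
#' @export
scheme_summary <- function(scheme) {
  stopifnot(inherits(scheme, "window_scheme"))
  list(n_windows_per_phase = nrow(scheme$phase_a),
       span_lower = scheme$span_lower,
       span_upper = scheme$span_upper,
       window_width = scheme$window_width,
       effective_width = scheme$window_width / 2,
       aligned_to_forbidden_zones = scheme$aligned_to_forbidden_zones)
}

#' Build a gas-phase fractionation (GPF) acquisition plan
#'
#' Splits the full precursor range across several injections of the same
#' sample. Injection k spans
#' `[full_lower + k*injection_step, full_lower + k*injection_step + injection_span)`;
#' at the defaults (110 m/z span, 100 m/z step) consecutive injections
#' overlap by 10 m/z. Each injection carries its own staggered scheme of
#' `ms2_width` windows, giving `ms2_width/2` effective windows after
#' demultiplexing -- the narrow-window data used to build an
#' experiment-specific chromatogram library.
#'
#' @param full_lower,full_upper full precursor range in m/z.
#' @param injection_span width of each injection's MS1 range (default 110).
#' @param injection_step offset between consecutive injections (default 100).
#' @param ms2_width isolation-window width inside each injection (default 4).
#' @param align,params forwarded to [build_staggered_scheme()].
#' @return A `gpf_plan` object: list with `injections` (data frame of
#'   `injection_lower`, `injection_upper`) and `schemes` (list of
#'   `window_scheme`, one per injection).
#' @examples
#' plan <- build_gpf_plan(394.8, 1104.8)
#' nrow(plan$injections)  # 7
#' @export
build_gpf_plan <- function(full_lower, full_upper, injection_span = 110,
                           injection_step = 100, ms2_width = 4,
                           align = FALSE, params = forbidden_zone_params()) {
  assert_number(full_lower, "full_lower", lower = 0)
  assert_number(full_upper, "full_upper")
  assert_number(injection_span, "injection_span")
  assert_number(injection_step, "injection_step")
  if (injection_step <= 0) stop2("'injection_step' must be positive")
  if (injection_step > injection_span)
    stop2("'injection_step' must not exceed 'injection_span' (ranges must tile)")
  range_width <- full_upper - full_lower
  if (range_width < injection_span)
    stop2("full range narrower than 'injection_span'")
  k_max <- as.integer(ceiling((range_width - injection_span) / injection_step - 1e-9))
  starts <- full_lower + injection_step * (0:k_max)
  inj <- data.frame(injection_lower = starts,
                    injection_upper = starts + injection_span)
  schemes <- lapply(seq_len(nrow(inj)), function(i)
    build_staggered_scheme(inj$injection_lower[i], inj$injection_upper[i],
                           ms2_width, align = align, params = params))
  structure(list(injections = inj, schemes = schemes,
                 injection_span = injection_span,
                 injection_step = injection_step,
                 ms2_width = ms2_width),
            class = "gpf_plan")
}

#' @export
print.gpf_plan <- function(x, ...) {
  cat(sprintf("GPF plan: %d injections of %g m/z (step %g), %g m/z MS2 windows\n",
              nrow(x$injections), x$injection_span, x$injection_step, x$ms2_width))
  for (i in seq_len(nrow(x$injections)))
    cat(sprintf("  injection %d: %.1f to %.1f m/z\n", i,
                x$injections$injection_lower[i], x$injections$injection_upper[i]))
  invisible(x)
}

#' Export a window scheme as an instrument-style inclusion list
#'
#' Writes a CSV with columns `center_mz`, `width_mz`, `phase` in acquisition
#' order (phase A first), values printed with 6 decimal places.
#'
#' @param scheme a `window_scheme`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_window_list <- function(scheme, path) {
  stopifnot(inherits(scheme, "window_scheme"))
  rows <- rbind(
    data.frame(center_mz = (scheme$phase_a$lower + scheme$phase_a$upper) / 2,
               width_mz = scheme$phase_a$upper - scheme$phase_a$lower,
               phase = "a"),
    data.frame(center_mz = (scheme$phase_b$lower + scheme$phase_b$upper) / 2,
               width_mz = scheme$phase_b$upper - scheme$phase_b$lower,
               phase = "b"))
  rows$center_mz <- sprintf("%.6f", rows$center_mz)
  rows$width_mz <- sprintf("%.6f", rows$width_mz)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
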