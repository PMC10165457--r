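#' Effective half-width windows of a staggered scheme
#'
#' A staggered scheme interleaves two grids offset by half a window width,
#' so after demultiplexing the precursor axis is resolved into contiguous
#' "effective" windows of width `window_width / 2` covering the span. Each
#' staggered window covers exactly two consecutive effective windows.
#'
#' @param scheme a `window_scheme` built by [build_staggered_scheme()].
#' @return Data frame with columns `index`, `lower`, `upper` and a logical
#'   `boundary` marking effective windows covered by scans of only one
#'   phase (the half-windows at the span edges).
#' @examples
#' eff <- effective_windows(build_staggered_scheme(394.8, 504.8, 4))
#' nrow(eff)  # 55
#' @export
effective_windows <- function(scheme) {
  stopifnot(inherits(scheme, "window_scheme"))
  if (is.null(scheme$phase_b) || nrow(scheme$phase_b) == 0L)
    stop2("scheme is not staggered: no phase-b windows")
  half <- scheme$window_width / 2
  span <- scheme$span_upper - scheme$span_lower
  n_eff <- max(2L, as.integer(ceiling(span / half - 1e-9)))
  lower <- scheme$span_lower + half * (seq_len(n_eff) - 1L)
  out <- data.frame(index = seq_len(n_eff), lower = lower, upper = lower + half)
  # phase a window k covers eff {2k-1, 2k}; phase b window k covers {2k, 2k+1}.
  # eff j is covered by phase a iff ceil(j/2) <= n and by phase b iff j >= 2,
  # so only the first half-window is single-phase (flagged as boundary).
  out$boundary <- out$index == 1L
  out
}

# Lawson-Hanson active-set nonnegative least squares: min ||Ax - b||, x >= 0
nnls_solve <- function(A, b, tol = 1e-9) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive) && max(w[!passive]) > tol * max(1, max(abs(b)))) {
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      z[passive][is.na(z[passive])] <- 0
      if (all(z[passive] > tol)) break
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- z
    w <- crossprod(A, b - A %*% x)
    iter <- iter + 1L
    if (iter > 5L * n) break  # defensive cap; active set cycling is rare
  }
  pmax(x, 0)
}

# map scans to (phase, window index) against the scheme grid
match_scans <- function(scans, scheme, tol = 1e-6) {
  need <- c("cycle", "phase", "window_lower", "window_upper",
            "fragment_channel", "intensity")
  missing_cols <- setdiff(need, names(scans))
  if (length(missing_cols))
    stop2("scan table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (any(scans$intensity < 0))
    stop2("negative observed intensity in scan table")
  idx <- integer(nrow(scans))
  for (ph in c("a", "b")) {
    grid <- if (ph == "a") scheme$phase_a else scheme$phase_b
    sel <- scans$phase == ph
    m <- match(round(scans$window_lower[sel], 6), round(grid$lower, 6))
    if (anyNA(m))
      stop2("scan windows do not conform to the scheme grid (phase ", ph, ")")
    if (any(abs(scans$window_upper[sel] - grid$upper[m]) > tol))
      stop2("scan window widths do not conform to the scheme grid (phase ", ph, ")")
    idx[sel] <- m
  }
  idx
}

#' Demultiplex staggered DIA scan cycles into effective windows
#'
#' Each staggered scan observes the summed intensity of the two effective
#' half-windows it covers. Per cycle and fragment channel the demultiplexer
#' solves the resulting banded nonnegative least-squares system over all
#' scans of the cycle, with half-windows beyond the span constrained to
#' zero (which makes the system determined). On noiseless input in which
#' every analyte occupies a single effective window the estimates recover
#' the ground truth exactly; with noise, the nonnegativity constraint
#' regularises the solution.
#'
#' @param cycles scan table (see [simulate_scan_cycles()]): columns `cycle`,
#'   `phase` (`"a"`/`"b"`), `window_lower`, `window_upper`,
#'   `fragment_channel`, `intensity`.
#' @param scheme the `window_scheme` the scans were acquired with
#'   (unaligned grid; the demultiplexer works on the nominal geometry).
#' @return Data frame with columns `cycle`, `fragment_channel`,
#'   `effective_index`, `effective_lower`, `effective_upper`, `intensity`,
#'   `boundary`. Intensities are nonnegative.
#' @export
demultiplex <- function(cycles, scheme) {
  stopifnot(inherits(scheme, "window_scheme"))
  eff <- effective_windows(scheme)
  n_eff <- nrow(eff)
  if (length(unique(cycles$cycle)) < 2L)
    stop2("demultiplexing requires at least 2 scan cycles")
  widx <- match_scans(cycles, scheme)

  # design matrix over one full duty cycle (all scans of both phases)
  key <- paste(cycles$phase, widx)
  scan_keys <- unique(key)
  A <- matrix(0, nrow = length(scan_keys), ncol = n_eff)
  for (i in seq_along(scan_keys)) {
    parts <- strsplit(scan_keys[i], " ", fixed = TRUE)[[1]]
    k <- as.integer(parts[2])
    cov <- if (parts[1] == "a") c(2L * k - 1L, 2L * k) else c(2L * k, 2L * k + 1L)
    cov <- cov[cov >= 1L & cov <= n_eff]  # out-of-span halves constrained to 0
    A[i, cov] <- 1
  }

  out <- list()
  for (cy in sort(unique(cycles$cycle))) {
    sub <- cycles[cycles$cycle == cy, , drop = FALSE]
    kidx <- match(paste(sub$phase, widx[cycles$cycle == cy]), scan_keys)
    for (ch in unique(sub$fragment_channel)) {
      b <- numeric(length(scan_keys))
      rows <- sub$fragment_channel == ch
      b[kidx[rows]] <- sub$intensity[rows]
      x <- nnls_solve(A, b)
      out[[length(out) + 1L]] <- data.frame(
        cycle = cy, fragment_channel = ch,
        effective_index = eff$index, effective_lower = eff$lower,
        effective_upper = eff$upper, intensity = x,
        boundary = eff$boundary)
    }
  }
  do.call(rbind, out)
}
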