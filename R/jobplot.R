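#' Continuous-variation (Job plot) series container
#'
#' A Job series varies the RNA:ligand mixing ratio at fixed total
#' concentration; the signal change peaks at the mole fraction matching
#' the complex stoichiometry.
#'
#' @param mole_fraction_rna Mole fractions x = cRNA/(cRNA + cL) in
#'   \[0, 1\], length >= 5.
#' @param delta_signal Signal change (F0 - FF) per mixing ratio.
#' @param total_conc Fixed total concentration cRNA + cL (molar, > 0).
#' @return A `job_series` object.
#' @export
job_series <- function(mole_fraction_rna, delta_signal, total_conc) {
  x <- as.numeric(mole_fraction_rna)
  y <- as.numeric(delta_signal)
  if (length(x) != length(y)) stop("job_series: lengths differ")
  if (length(x) < 5) stop("job_series: need at least 5 points")
  if (any(x < 0 | x > 1)) stop("job_series: mole fractions must lie in [0, 1]")
  if (!is.finite(total_conc) || total_conc <= 0)
    stop("job_series: total_conc must be > 0")
  structure(list(mole_fraction_rna = x, delta_signal = y,
                 total_conc = total_conc),
            class = "job_series")
}

#' Index of the empirical Job-plot maximum
#'
#' Ties are broken toward the smaller mole fraction; a maximum on the
#' boundary of the series triggers a warning (the peak may lie outside
#' the sampled range).
#'
#' @param series A [job_series()].
#' @return Integer index of the largest `delta_signal`.
#' @export
find_peak <- function(series) {
  stopifnot(inherits(series, "job_series"))
  y <- series$delta_signal
  if (length(unique(y)) == 1L)
    stop("find_peak: degenerate series (all signals equal)")
  ord <- order(series$mole_fraction_rna)
  idx_sorted <- ord[which.max(y[ord])]  # smallest x among tied maxima
  if (idx_sorted == ord[1L] || idx_sorted == ord[length(ord)])
    warning("find_peak: maximum on the boundary of the series")
  idx_sorted
}

#' Stoichiometry by tangent intersection on a Job plot
#'
#' Fits an ordinary least-squares line to each flank of the peak-shaped
#' curve (after dropping points within `exclusion_halfwidth` of the
#' empirical peak mole fraction) and intersects the two lines. The
#' intersection abscissa `x_max` gives the binding stoichiometry
#' `m = (1 - x_max)/x_max` ligands per RNA.
#'
#' @param series A [job_series()].
#' @param exclusion_halfwidth Half-width (in mole fraction) of the window
#'   around the empirical peak excluded from the tangents.
#' @param min_points Minimum flank points required on each side.
#' @return A `job_result`: `x_max`, `stoichiometry_m`,
#'   `stoichiometry_nearest` (nearest integer), `left_line`,
#'   `right_line` (slope/intercept), `points_used_left/right`.
#' @export
tangent_intersection <- function(series, exclusion_halfwidth = 0.08,
                                 min_points = 3) {
  stopifnot(inherits(series, "job_series"))
  x <- series$mole_fraction_rna
  y <- series$delta_signal
  xpk <- x[find_peak(series)]
  keep <- abs(x - xpk) > exclusion_halfwidth
  left <- keep & x < xpk
  right <- keep & x > xpk
  if (sum(left) < min_points || sum(right) < min_points)
    stop("tangent_intersection: fewer than ", min_points,
         " flank points on one side after peak exclusion")
  fl <- lm(y[left] ~ x[left])
  fr <- lm(y[right] ~ x[right])
  ml <- unname(coef(fl)[2L]); bl <- unname(coef(fl)[1L])
  mr <- unname(coef(fr)[2L]); br <- unname(coef(fr)[1L])
  if (abs(ml - mr) < 1e-12 * max(abs(ml), abs(mr), 1))
    stop("tangent_intersection: tangents are parallel")
  x_max <- (br - bl) / (ml - mr)
  if (!(x_max > 0 && x_max < 1))
    stop("tangent_intersection: intersection outside (0, 1)")
  m <- (1 - x_max) / x_max
  structure(list(x_max = x_max,
                 stoichiometry_m = m,
                 stoichiometry_nearest = round(m),
                 left_line = c(slope = ml, intercept = bl),
                 right_line = c(slope = mr, intercept = br),
                 points_used_left = sum(left),
                 points_used_right = sum(right)),
            class = "job_result")
}

#' @export
print.job_result <- function(x, ...) {
  cat(sprintf("Job plot: x_max = %.4f -> %.2f ligands per RNA (~%d:1)\n",
              x$x_max, x$stoichiometry_m, x$stoichiometry_nearest))
  invisible(x)
}

#' Stoichiometry from the Job-plot maximum
#'
#' `m = (1 - x_max)/x_max` ligands per RNA; `x_max = 1/2` for 1:1 and
#' `x_max = 1/3` for 2:1 binding.
#'
#' @param x_max Mole fraction of RNA at the maximum, in (0, 1).
#' @return Ligands per RNA (real).
#' @export
stoichiometry_from_xmax <- function(x_max) {
  if (any(x_max <= 0 | x_max >= 1))
    stop("stoichiometry_from_xmax: x_max must lie in (0, 1)")
  (1 - x_max) / x_max
}
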