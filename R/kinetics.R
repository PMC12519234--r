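#' Stopped-flow kinetic trace container
#'
#' One association time course at a fixed post-mix ligand concentration.
#' When the ligand is not in clear excess over the RNA (under 4x), a
#' pseudo-first-order warning is attached rather than an error, since
#' useful designs sometimes approach the limit.
#'
#' @param time_s Strictly increasing times (seconds, >= 0).
#' @param signal Fluorescence (arbitrary units), same length.
#' @param ligand_conc Post-mix ligand concentration (molar).
#' @param rna_conc Post-mix RNA concentration (molar).
#' @return A `kinetic_trace` object.
#' @export
kinetic_trace <- function(time_s, signal, ligand_conc, rna_conc) {
  time_s <- as.numeric(time_s)
  signal <- as.numeric(signal)
  if (length(time_s) != length(signal))
    stop("kinetic_trace: time and signal lengths differ")
  if (any(time_s < 0) || any(diff(time_s) <= 0))
    stop("kinetic_trace: times must be strictly increasing from >= 0")
  pfo <- ligand_conc > rna_conc
  if (ligand_conc < 4 * rna_conc)
    warning("kinetic_trace: ligand < 4x RNA post-mix; ",
            "pseudo-first-order approximation is marginal")
  structure(list(time_s = time_s, signal = signal,
                 ligand_conc = ligand_conc, rna_conc = rna_conc,
                 pseudo_first_order = pfo),
            class = "kinetic_trace")
}

#' Fit a single-exponential association trace
#'
#' Fits `F = A * (1 - exp(-kobs * t))` on the raw signal scale with the
#' amplitude free and the observed rate constrained positive via log10
#' parameterization. A trace with zero signal variance returns
#' `converged = FALSE`; a net-decreasing signal yields a negative fitted
#' amplitude with a warning.
#'
#' @param trace A [kinetic_trace()], or any list with `time_s` and
#'   `signal`.
#' @param control See [fit_control()].
#' @return A `fit_result` with estimates `A` and `kobs` (s^-1).
#' @export
fit_trace <- function(trace, control = fit_control()) {
  t <- trace$time_s
  y <- trace$signal
  if (length(t) < 10)
    stop("fit_trace: need at least 10 points")
  if (sd(y) == 0) {
    nm <- c("A", "kobs")
    return(structure(list(
      estimates = setNames(c(NA_real_, NA_real_), nm),
      standard_errors = setNames(c(NA_real_, NA_real_), nm),
      covariance = matrix(NA_real_, 2, 2, dimnames = list(nm, nm)),
      rss = 0, n_points = length(y), n_params = 2L,
      converged = FALSE, n_iterations = 0L, seed_used = NULL),
      class = "fit_result"))
  }
  span <- diff(range(t))
  ## crude rate guess from time to half the final level
  yend <- mean(tail(y, max(3L, length(y) %/% 20)))
  ihalf <- which(abs(y - yend / 2) == min(abs(y - yend / 2)))[1L]
  thalf <- max(t[ihalf], span / 200)
  k0 <- log(2) / thalf
  model <- function(p, tt) p[["A"]] * (1 - exp(-p[["kobs"]] * tt))
  specs <- list(
    param_spec("A", if (abs(yend) > 0) yend else max(abs(y)),
               lower = -1e6, upper = 1e6),
    param_spec("kobs", k0, lower = 1e-8, upper = 1e4, log_scale = TRUE))
  fit <- nls_fit(model, t, y, specs, control = control)
  if (fit$converged && fit$estimates[["A"]] < 0)
    warning("fit_trace: negative fitted amplitude (decreasing signal)")
  if (fit$converged && fit$estimates[["kobs"]] * span < 1)
    warning("fit_trace: trace shorter than 1/kobs; rate poorly determined")
  fit
}

#' Association rate from kobs-versus-concentration regression
#'
#' Weighted linear regression `kobs = kon * cL + d`; the slope is the
#' bimolecular association rate constant and the intercept `d` estimates
#' the dissociation rate in the pseudo-first-order scheme. Weights are
#' `1/SE^2` when standard errors are available.
#'
#' @param points A data.frame with columns `ligand_conc` (molar), `kobs`
#'   (s^-1) and optionally `kobs_se`.
#' @return A `rate_params` list: `kon`, `kon_se` (M^-1 s^-1),
#'   `intercept`, `intercept_se` (s^-1), `koff = NA`, `kd_used = NA`, and
#'   the underlying `lm` fit.
#' @export
fit_kon <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("ligand_conc", "kobs") %in% names(points)))
  if (length(unique(points$ligand_conc)) < 2)
    stop("fit_kon: need at least 2 distinct ligand concentrations")
  w <- if ("kobs_se" %in% names(points) &&
           all(is.finite(points$kobs_se)) && all(points$kobs_se > 0))
    1 / points$kobs_se^2 else NULL
  fit <- lm(kobs ~ ligand_conc, data = points, weights = w)
  # summary.lm warns on exactly interpolating data; harmless here
  cf <- suppressWarnings(coef(summary(fit)))
  kon <- cf["ligand_conc", "Estimate"]
  if (kon <= 0)
    warning("fit_kon: nonpositive slope; kon is nonphysical for this data")
  structure(list(kon = kon,
                 kon_se = cf["ligand_conc", "Std. Error"],
                 intercept = cf["(Intercept)", "Estimate"],
                 intercept_se = cf["(Intercept)", "Std. Error"],
                 koff = NA_real_, kd_used = NA_real_, lm_fit = fit),
            class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Association kinetics (kobs = kon * cL + d)\n")
  cat(sprintf("  kon       = %.4g +/- %.2g  M^-1 s^-1\n", x$kon, x$kon_se))
  cat(sprintf("  intercept = %.4g +/- %.2g  s^-1\n",
              x$intercept, x$intercept_se))
  if (is.finite(x$koff))
    cat(sprintf("  koff      = %.4g s^-1 (from KD = %.4g M)\n",
                x$koff, x$kd_used))
  invisible(x)
}

#' Dissociation rate from kinetic-thermodynamic consistency
#'
#' `koff = kon * KD`, combining the measured association rate with the
#' equilibrium dissociation constant.
#'
#' @param kon Association rate constant (M^-1 s^-1, > 0).
#' @param kd Equilibrium dissociation constant (molar, > 0).
#' @return Dissociation rate (s^-1).
#' @examples
#' koff_from_equilibrium(1.16e3, 0.62e-6)  # ~7.2e-4 s^-1
#' @export
koff_from_equilibrium <- function(kon, kd) {
  if (kon <= 0 || kd <= 0)
    stop("koff_from_equilibrium: kon and kd must be > 0")
  kon * kd
}

#' Complex half-life in minutes
#'
#' `t_1/2 = ln(2) / koff`, reported in minutes.
#'
#' @param koff Dissociation rate (s^-1, > 0).
#' @return Half-life in minutes.
#' @examples
#' half_life(7.5e-4)  # ~15.4 min
#' @export
half_life <- function(koff) {
  if (any(koff <= 0)) stop("half_life: koff must be > 0")
  log(2) / koff / 60
}

#' Simulated complex dissociation with confidence band
#'
#' Fraction of complex remaining, `exp(-koff * t)`, with a 95% band from
#' perturbing the rate by +/- 1.96 standard errors (rates clamped at 0 so
#' the band never exceeds 1).
#'
#' @param koff Dissociation rate (s^-1, > 0).
#' @param koff_se Standard error of the rate (>= 0).
#' @param times Time grid (seconds).
#' @return data.frame with `time_s`, `fraction`, `lower`, `upper`.
#' @export
simulate_decay <- function(koff, koff_se, times) {
  if (koff <= 0) stop("simulate_decay: koff must be > 0")
  if (koff_se < 0) stop("simulate_decay: koff_se must be >= 0")
  k_hi <- koff + 1.96 * koff_se
  k_lo <- max(koff - 1.96 * koff_se, 0)
  data.frame(time_s = times,
             fraction = exp(-koff * times),
             lower = exp(-k_hi * times),
             upper = exp(-k_lo * times))
}

#' Full stopped-flow pipeline: traces to association rate
#'
#' Fits each trace to the single-exponential model, assembles the kobs
#' table, and regresses kobs on ligand concentration.
#'
#' @param traces List of [kinetic_trace()] objects.
#' @param kd Optional equilibrium KD (molar); when given, `koff` is
#'   derived as `kon * kd`.
#' @return A list with `kobs_table` (data.frame), `rate` (`rate_params`)
#'   and `trace_fits` (list of `fit_result`).
#' @export
analyze_kinetics <- function(traces, kd = NULL) {
  fits <- lapply(traces, fit_trace)
  tab <- data.frame(
    ligand_conc = vapply(traces, `[[`, 0, "ligand_conc"),
    kobs = vapply(fits, function(f) unname(f$estimates[["kobs"]]), 0),
    kobs_se = vapply(fits, function(f) unname(f$standard_errors[["kobs"]]), 0))
  rate <- fit_kon(tab)
  if (!is.null(kd)) {
    rate$koff <- koff_from_equilibrium(rate$kon, kd)
    rate$kd_used <- kd
  }
  list(kobs_table = tab, rate = rate, trace_fits = fits)
}
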