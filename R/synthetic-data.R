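#' Noise specification for synthetic assays
#'
#' Additive Gaussian noise whose standard deviation is expressed as a
#' fraction of the assay's full dynamic range (for ITC, of the magnitude
#' of the first-injection heat).
#'
#' @param sd Noise SD as a fraction of dynamic range (>= 0).
#' @param seed Integer seed; required whenever `sd > 0`.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(sd = 0, seed = NULL) {
  if (sd < 0) stop("noise_spec: sd must be >= 0")
  if (sd > 0 && is.null(seed))
    stop("noise_spec: a seed is required when sd > 0")
  structure(list(kind = "additive_gaussian", sd = sd, seed = seed),
            class = "noise_spec")
}

## internal: add seeded Gaussian noise scaled to `scale`
.add_noise <- function(x, noise, scale) {
  if (noise$sd == 0) return(x)
  with_seed(noise$seed, x + rnorm(length(x), 0, noise$sd * scale))
}

#' Generate a synthetic equilibrium titration
#'
#' Evaluates the chosen binding model on a ligand series and adds seeded
#' Gaussian noise. Defaults reproduce the standard design: 0.5 uM RNA
#' titrated over 0-45 uM ligand (see [titration_ligand_series()]).
#'
#' @param model_kind `"quadratic_single_site"`, `"hill"` or `"two_site"`.
#' @param true_params Named list of ground-truth parameters for the
#'   model: single site `kd`, `amplitude`, `baseline`; Hill `kd_av`,
#'   `hill_n`, `amplitude`; two-site `kd1`, `kd2`, `amplitude`.
#' @param ligand_series Molar ligand concentrations.
#' @param rna_total Molar RNA concentration.
#' @param noise A [noise_spec()].
#' @return An [equilibrium_titration()] with the ground truth attached
#'   as attribute `"truth"`.
#' @export
gen_titration <- function(model_kind = c("quadratic_single_site", "hill",
                                         "two_site"),
                          true_params,
                          ligand_series = titration_ligand_series(),
                          rna_total = 0.5e-6,
                          noise = noise_spec()) {
  model_kind <- match.arg(model_kind)
  defaults <- switch(model_kind,
    quadratic_single_site = list(amplitude = 1, baseline = 0),
    hill = list(amplitude = 1),
    two_site = list(amplitude = 1))
  p <- modifyList(defaults, true_params)
  model <- .titration_model(model_kind, rna_total, free_ligand_mode = FALSE)
  pv <- unlist(p)
  y <- model(pv, ligand_series)
  y <- .add_noise(y, noise, abs(diff(range(y))))
  out <- equilibrium_titration(ligand_series, y, rna_total,
                               label = paste0("synthetic-", model_kind))
  attr(out, "truth") <- p
  out
}

#' Generate synthetic stopped-flow traces
#'
#' One association trace per post-mix ligand concentration:
#' `signal = A * (1 - exp(-(kon*cL + koff) * t))` with A = 1, plus
#' seeded Gaussian noise. Defaults follow the standard design: 700 s
#' traces at post-mix ligand 1, 2, 6, 10 uM against 0.5 uM RNA.
#'
#' @param kon Association rate constant (M^-1 s^-1, > 0).
#' @param koff Dissociation rate constant (s^-1, > 0).
#' @param rna_postmix Post-mix RNA concentration (molar).
#' @param ligand_series Post-mix ligand concentrations (molar).
#' @param duration_s Trace length (seconds).
#' @param dt_s Sampling interval (seconds, < duration).
#' @param noise A [noise_spec()]; SD is a fraction of the amplitude.
#' @return List of [kinetic_trace()] objects with attribute `"truth"`.
#' @export
gen_traces <- function(kon, koff, rna_postmix = 0.5e-6,
                       ligand_series = c(1, 2, 6, 10) * 1e-6,
                       duration_s = 700, dt_s = 1,
                       noise = noise_spec()) {
  if (kon <= 0 || koff <= 0) stop("gen_traces: kon and koff must be > 0")
  if (dt_s >= duration_s) stop("gen_traces: dt must be smaller than duration")
  t <- seq(0, duration_s, by = dt_s)
  kobs <- kon * ligand_series + koff
  make <- function(i, eps) {
    y <- 1 - exp(-kobs[i] * t) + eps
    suppressWarnings(kinetic_trace(t, y, ligand_series[i], rna_postmix))
  }
  traces <- if (noise$sd == 0) {
    lapply(seq_along(ligand_series), make, eps = 0)
  } else {
    with_seed(noise$seed, lapply(seq_along(ligand_series), function(i)
      make(i, rnorm(length(t), 0, noise$sd))))
  }
  attr(traces, "truth") <- list(kon = kon, koff = koff, kobs = kobs)
  traces
}

#' Generate a synthetic Job (continuous variation) series
#'
#' At each mixing ratio on a fixed-total grid, the signal change is
#' computed from the exact species solution (no excess-ligand
#' approximation), normalized to a unit maximum, plus seeded noise.
#' The default grid mirrors the standard design: 11 ratios with
#' cRNA + cL = 20 uM.
#'
#' For the two-site model the default readout is the total bound ligand
#' `R * nu(L_free)` -- every binding event contributes equally to the
#' fluorescence change, the same convention as [twosite_signal()]. In
#' the strong-binding limit this readout is piecewise linear with its
#' apex exactly at mole fraction `1/(1+m)` irrespective of the stepwise
#' constants' ratio. The alternative `readout = "saturated_complex"`
#' (signal from the fully bound species only) coincides with it only
#' under strong positive cooperativity: with comparable stepwise
#' constants the singly bound intermediate accumulates on the
#' RNA-excess flank, curving it and biasing the tangent intersection
#' below the stoichiometric point.
#'
#' @param model `"single_site"` or `"two_site"`.
#' @param true_kds Numeric: `kd` for single site, `c(kd1, kd2)` for
#'   two-site (molar).
#' @param total_conc Fixed total concentration (molar).
#' @param n_points Number of equally spaced mixing ratios (>= 5).
#' @param noise A [noise_spec()].
#' @param readout Two-site signal convention: `"occupancy"` (default)
#'   or `"saturated_complex"`.
#' @return A [job_series()] with attribute `"truth"`.
#' @export
gen_job <- function(model = c("single_site", "two_site"), true_kds,
                    total_conc = 20e-6, n_points = 11,
                    noise = noise_spec(),
                    readout = c("occupancy", "saturated_complex")) {
  model <- match.arg(model)
  readout <- match.arg(readout)
  if (n_points < 5) stop("gen_job: need at least 5 points")
  x <- seq(0, 1, length.out = n_points)
  r <- x * total_conc         # RNA
  l <- (1 - x) * total_conc   # ligand
  complex <- if (model == "single_site") {
    s <- true_kds[1L] + r + l
    (s - sqrt(pmax(s^2 - 4 * r * l, 0))) / 2   # [RL] = bound ligand, molar
  } else {
    kd1 <- true_kds[1L]; kd2 <- true_kds[2L]
    lf <- free_ligand(l, r, kd1, kd2)
    k1l <- lf / kd1
    k12l2 <- k1l * lf / kd2
    z <- 1 + k1l + k12l2
    if (readout == "occupancy") r * (k1l + 2 * k12l2) / z  # bound ligand
    else r * k12l2 / z                                     # [RL2]
  }
  y <- complex / max(complex)
  y <- .add_noise(y, noise, 1)
  out <- job_series(x, y, total_conc)
  attr(out, "truth") <- list(model = model, kds = true_kds)
  out
}

#' Generate a synthetic ITC thermogram
#'
#' Evaluates the chosen forward model's per-injection heats on a
#' schedule and adds seeded Gaussian noise with SD a fraction of the
#' first-injection heat magnitude.
#'
#' @param model_kind `"identical_sites"` or `"two_interdependent"`.
#' @param true_params Named list for [injection_heats()].
#' @param schedule An [injection_schedule()]; defaults to the 25 C
#'   design for identical sites and the 37 C design otherwise.
#' @param noise A [noise_spec()].
#' @return A [thermogram()] with attribute `"truth"`.
#' @export
gen_itc <- function(model_kind = c("identical_sites", "two_interdependent"),
                    true_params, schedule = NULL,
                    noise = noise_spec()) {
  model_kind <- match.arg(model_kind)
  if (is.null(schedule))
    schedule <- if (model_kind == "identical_sites") itc_schedule_25C()
                else itc_schedule_37C()
  q <- injection_heats(schedule, model_kind, true_params)
  q <- .add_noise(q, noise, abs(q[1L]))
  out <- thermogram(schedule, q)
  attr(out, "truth") <- true_params
  out
}
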