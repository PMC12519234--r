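#' Equilibrium titration container
#'
#' Holds one 2-aminopurine fluorescence titration: total ligand
#' concentrations, normalized signal (F - F0)/(Ff - F0), and the fixed
#' RNA concentration. All concentrations are molar.
#'
#' @param ligand_total Non-decreasing, nonnegative molar ligand series
#'   (length >= 4; first point may be 0).
#' @param signal Normalized fluorescence, same length.
#' @param rna_total RNA concentration (molar, > 0).
#' @param label Optional text label.
#' @return An `equilibrium_titration` object.
#' @export
equilibrium_titration <- function(ligand_total, signal, rna_total, label = "") {
  ligand_total <- as.numeric(ligand_total)
  signal <- as.numeric(signal)
  if (length(ligand_total) != length(signal))
    stop("equilibrium_titration: ligand and signal lengths differ")
  if (length(ligand_total) < 4)
    stop("equilibrium_titration: need at least 4 titration points")
  if (any(ligand_total < 0) || is.unsorted(ligand_total))
    stop("equilibrium_titration: ligand series must be nonnegative and non-decreasing")
  if (!is.finite(rna_total) || rna_total <= 0)
    stop("equilibrium_titration: rna_total must be > 0")
  structure(list(ligand_total = ligand_total, signal = signal,
                 rna_total = rna_total, label = label),
            class = "equilibrium_titration")
}

#' Exact single-site bound fraction with ligand depletion
#'
#' Fraction of RNA in complex for 1:1 binding, from the quadratic
#' solution of the mass balance (no excess-ligand approximation):
#' `(S - sqrt(S^2 - 4*R*L)) / (2*R)` with `S = KD + R + L`.
#'
#' @param kd Dissociation constant (molar, >= 0).
#' @param rna_total Total RNA (molar, > 0).
#' @param ligand_total Total ligand (molar, >= 0); vectorized.
#' @return Bound fraction in \[0, 1\].
#' @examples
#' quadratic_fraction_bound(0.62e-6, 0.5e-6, 45e-6)  # ~0.986
#' @export
quadratic_fraction_bound <- function(kd, rna_total, ligand_total) {
  if (any(c(kd, rna_total, ligand_total) < 0))
    stop("quadratic_fraction_bound: arguments must be nonnegative")
  if (rna_total <= 0) stop("quadratic_fraction_bound: rna_total must be > 0")
  s <- kd + rna_total + ligand_total
  disc <- pmax(s^2 - 4 * rna_total * ligand_total, 0)
  ## algebraically (s - sqrt(disc)) / (2 * rna_total); this form avoids
  ## the cancellation of s - sqrt(disc) far from saturation
  2 * ligand_total / (s + sqrt(disc))
}

#' Hill (cooperative) binding signal
#'
#' `d * L^n / (KD^n + L^n)`; half-saturates at `L = kd_av`.
#'
#' @param ligand Ligand concentrations (molar, >= 0); vectorized.
#' @param kd_av Average dissociation constant KD,av (molar, > 0).
#' @param hill_n Hill coefficient (> 0).
#' @param amplitude Saturating signal change `d`.
#' @return Signal sequence, monotone non-decreasing in `ligand` for
#'   positive `amplitude`.
#' @export
hill_signal <- function(ligand, kd_av, hill_n, amplitude = 1) {
  if (any(ligand < 0)) stop("hill_signal: ligand must be nonnegative")
  if (kd_av <= 0 || hill_n <= 0)
    stop("hill_signal: kd_av and hill_n must be > 0")
  r <- (ligand / kd_av)^hill_n
  amplitude * r / (1 + r)
}

#' Average occupancy of a two-site receptor
#'
#' Average number of ligands bound per RNA from the binding polynomial
#' `Z = 1 + K1*L + K1*K2*L^2` with stepwise association constants
#' `K_i = 1/KD_i`:
#' `nu = (K1*L + 2*K1*K2*L^2) / Z`, which runs from 0 to 2.
#'
#' @param kd1,kd2 Macroscopic stepwise dissociation constants (molar, > 0)
#'   of the first and second binding event.
#' @param ligand_free Free ligand concentration (molar, >= 0); vectorized.
#' @return Average ligands bound per RNA, in \[0, 2\].
#' @examples
#' twosite_occupancy(0.5e-6, 2.2e-6, 1e-6)  # ~0.977
#' @export
twosite_occupancy <- function(kd1, kd2, ligand_free) {
  if (kd1 <= 0 || kd2 <= 0)
    stop("twosite_occupancy: dissociation constants must be > 0")
  if (any(ligand_free < 0))
    stop("twosite_occupancy: ligand_free must be nonnegative")
  k1l <- ligand_free / kd1
  k12l2 <- k1l * ligand_free / kd2
  (k1l + 2 * k12l2) / (1 + k1l + k12l2)
}

#' Two-site binding-polynomial signal
#'
#' `amplitude * nu(L) / 2`, saturating at `amplitude` when both sites
#' fill.
#'
#' @inheritParams twosite_occupancy
#' @param ligand Ligand concentrations (molar); by convention the total
#'   ligand when used as a fit model (the field's customary
#'   approximation), or the free ligand in exact mode.
#' @param amplitude Saturating signal change `d`.
#' @return Signal sequence.
#' @export
twosite_signal <- function(ligand, kd1, kd2, amplitude = 1) {
  amplitude * twosite_occupancy(kd1, kd2, ligand) / 2
}

#' Exact free-ligand concentration for a two-site receptor
#'
#' Solves the mass balance `L + R * nu(L) = L_total` for the free ligand
#' L on `[0, L_total]`. Monotonicity of the left-hand side makes the root
#' unique; it is found by bisection to ~1e-15 relative precision.
#' Vectorized over `ligand_total`.
#'
#' @param ligand_total Total ligand (molar, >= 0); vectorized.
#' @param rna_total Total RNA (molar, >= 0); scalar or vectorized with
#'   `ligand_total`.
#' @param kd1,kd2 Stepwise dissociation constants (molar, > 0).
#' @return Free ligand concentration(s), molar.
#' @export
free_ligand <- function(ligand_total, rna_total, kd1, kd2) {
  if (any(ligand_total < 0) || any(rna_total < 0))
    stop("free_ligand: concentrations must be nonnegative")
  if (all(rna_total == 0)) return(ligand_total)
  lo <- rep(0, length(ligand_total))
  hi <- ligand_total
  for (i in seq_len(60)) {
    mid <- (lo + hi) / 2
    f <- mid + rna_total * twosite_occupancy(kd1, kd2, mid) - ligand_total
    up <- f <= 0
    lo <- ifelse(up, mid, lo)
    hi <- ifelse(up, hi, mid)
  }
  (lo + hi) / 2
}

#' Cooperativity factor of a two-site receptor
#'
#' `y = 4 * KD1 / KD2`. For independent identical sites the statistical
#' factor between the stepwise macroscopic constants is 4
#' (`KD2 = 4 * KD1`), so `y = 1`; `y < 1` indicates negative and `y > 1`
#' positive cooperativity.
#'
#' @inheritParams twosite_occupancy
#' @return Unitless cooperativity factor.
#' @examples
#' cooperativity_factor(0.65e-6, 3.12e-6)  # ~0.83, i.e. 0.8 to one decimal
#' @export
cooperativity_factor <- function(kd1, kd2) {
  if (kd1 <= 0 || kd2 <= 0)
    stop("cooperativity_factor: dissociation constants must be > 0")
  4 * kd1 / kd2
}

#' Normalize a raw fluorescence titration
#'
#' Maps raw integrated fluorescence to `(F - F0)/(Ff - F0)` using the
#' first and last points, so the result runs from 0 to 1 whether the raw
#' signal increases or decreases upon binding.
#'
#' @param raw Raw signal sequence (length >= 2).
#' @param direction `"auto"` (default), or the expected raw direction
#'   `"increase"`/`"decrease"`; a mismatch raises a warning only.
#' @return Normalized signal with first element 0 and last element 1.
#' @export
normalize_titration <- function(raw, direction = c("auto", "increase", "decrease")) {
  direction <- match.arg(direction)
  raw <- as.numeric(raw)
  if (length(raw) < 2) stop("normalize_titration: need at least 2 points")
  f0 <- raw[1L]
  ff <- raw[length(raw)]
  if (ff == f0)
    stop("normalize_titration: degenerate input (no signal change between endpoints)")
  if (direction == "increase" && ff < f0)
    warning("normalize_titration: raw signal decreases but direction = 'increase'")
  if (direction == "decrease" && ff > f0)
    warning("normalize_titration: raw signal increases but direction = 'decrease'")
  (raw - f0) / (ff - f0)
}

## internal: model curve factories for fit_titration
.titration_model <- function(model_kind, rna_total, free_ligand_mode,
                             literal_form = FALSE) {
  switch(model_kind,
    quadratic_single_site = function(p, L) {
      if (literal_form) {
        ## the legacy printed form divides the quadratic numerator by
        ## (2*cRNA - d); kept only for comparison with historical fits
        s <- p[["kd"]] + rna_total + L
        num <- s - sqrt(pmax(s^2 - 4 * rna_total * L, 0))
        num / (2 * rna_total - p[["baseline"]])
      } else {
        p[["amplitude"]] *
          quadratic_fraction_bound(p[["kd"]], rna_total, L) + p[["baseline"]]
      }
    },
    hill = function(p, L) {
      hill_signal(L, p[["kd_av"]], p[["hill_n"]], p[["amplitude"]])
    },
    two_site = function(p, L) {
      Lx <- if (free_ligand_mode)
        free_ligand(L, rna_total, p[["kd1"]], p[["kd2"]]) else L
      twosite_signal(Lx, p[["kd1"]], p[["kd2"]], p[["amplitude"]])
    },
    stop("unknown titration model: ", model_kind))
}

## internal: default parameter specs for each titration model
.titration_specs <- function(model_kind, curve) {
  L <- curve$ligand_total
  y <- curve$signal
  lpos <- L[L > 0]
  kmid <- if (length(lpos)) exp(mean(log(range(lpos)))) else 1e-6
  amp0 <- max(abs(diff(range(y))), 0.1)
  kspec <- function(nm, init) {
    param_spec(nm, init, lower = 1e-12, upper = 1e-1, log_scale = TRUE)
  }
  switch(model_kind,
    quadratic_single_site = list(
      kspec("kd", kmid),
      param_spec("amplitude", amp0, lower = -10, upper = 10),
      param_spec("baseline", 0, lower = -2, upper = 2)),
    hill = list(
      kspec("kd_av", kmid),
      param_spec("hill_n", 1.5, lower = 0.2, upper = 8),
      param_spec("amplitude", amp0, lower = -10, upper = 10)),
    two_site = list(
      kspec("kd1", kmid / 4),
      kspec("kd2", kmid * 4),
      param_spec("amplitude", amp0, lower = -10, upper = 10)))
}

#' Fit an equilibrium titration
#'
#' Fits one of three equilibrium models to a normalized titration:
#'
#' * `"quadratic_single_site"`: exact 1:1 isotherm with ligand depletion,
#'   `amplitude * fraction_bound(KD) + baseline`;
#' * `"hill"`: cooperative Hill model with free Hill coefficient;
#' * `"two_site"`: binding-polynomial model for two sequential binding
#'   events, reported as macroscopic stepwise KD,1 and KD,2.
#'
#' Affinity constants are fit in log10 space. By default the two-site and
#' Hill abscissa is the *total* ligand concentration (the customary
#' approximation when ligand is in excess of the RNA); set
#' `free_ligand_mode = TRUE` to use the exact free-ligand mass balance
#' for the two-site model instead.
#'
#' @param curve An [equilibrium_titration()].
#' @param model_kind One of `"quadratic_single_site"`, `"hill"`,
#'   `"two_site"`.
#' @param free_ligand_mode Use exact free ligand for the two-site model?
#' @param literal_form Use the legacy printed single-site normalization
#'   `(... )/(2*cRNA - d)` instead of `amplitude * fraction + baseline`?
#' @param specs Optional list of [param_spec()] overriding the defaults.
#' @param control See [fit_control()].
#' @return A `fit_result`; for `"two_site"` the cooperativity factor `y`
#'   is attached as `$cooperativity_y`.
#' @export
fit_titration <- function(curve,
                          model_kind = c("quadratic_single_site", "hill",
                                         "two_site"),
                          free_ligand_mode = FALSE,
                          literal_form = FALSE,
                          specs = NULL,
                          control = fit_control()) {
  stopifnot(inherits(curve, "equilibrium_titration"))
  model_kind <- match.arg(model_kind)
  if (is.null(specs)) specs <- .titration_specs(model_kind, curve)
  if (length(curve$signal) < length(specs) + 1)
    stop("fit_titration: need at least n_params + 1 points")
  model <- .titration_model(model_kind, curve$rna_total, free_ligand_mode,
                            literal_form)
  fit <- nls_fit(model, curve$ligand_total, curve$signal, specs,
                 control = control)
  fit$model_kind <- model_kind
  if (model_kind == "two_site" && fit$converged)
    fit$cooperativity_y <- cooperativity_factor(fit$estimates[["kd1"]],
                                                fit$estimates[["kd2"]])
  fit
}

#' Default equilibrium titration design
#'
#' The standard ligand series used throughout: 0, 0.1, 0.2, 0.4, 0.6, 1,
#' 2, 4, 6, 10, 15, 25, 35, 45 uM at 0.5 uM RNA.
#'
#' @return Molar ligand concentrations.
#' @export
titration_ligand_series <- function() {
  c(0, 0.1, 0.2, 0.4, 0.6, 1, 2, 4, 6, 10, 15, 25, 35, 45) * 1e-6
}
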