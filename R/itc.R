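#' ITC injection schedule
#'
#' Geometry and concentrations of a titration calorimetry run on a
#' fixed-volume perfusion cell (iTC200-style, 200 uL cell).
#'
#' @param injection_volumes Per-injection volumes (liters).
#' @param syringe_conc Ligand concentration in the syringe (molar).
#' @param cell_conc Macromolecule (RNA) concentration in the cell (molar).
#' @param cell_volume Working cell volume V0 (liters; default 200 uL).
#' @param temperature Kelvin (metadata only).
#' @return An `injection_schedule` object.
#' @export
injection_schedule <- function(injection_volumes, syringe_conc, cell_conc,
                               cell_volume = 200e-6, temperature = 298.15) {
  dv <- as.numeric(injection_volumes)
  if (any(dv <= 0)) stop("injection_schedule: injection volumes must be > 0")
  if (cell_volume <= 0) stop("injection_schedule: cell volume must be > 0")
  if (sum(dv) >= cell_volume)
    stop("injection_schedule: cumulative injected volume must stay below the cell volume")
  if (syringe_conc <= 0 || cell_conc <= 0)
    stop("injection_schedule: concentrations must be > 0")
  structure(list(cell_volume = cell_volume, injection_volumes = dv,
                 syringe_conc = syringe_conc, cell_conc = cell_conc,
                 temperature = temperature),
            class = "injection_schedule")
}

#' Standard iTC200 schedules
#'
#' Convenience constructors for the two designs used throughout:
#' 20 x 2 uL injections of 1.84 mM ligand into 73 uM RNA at 25 C, and
#' 30 x 1.3 uL injections of 1.15 mM ligand into 48 uM RNA at 37 C.
#'
#' @return An [injection_schedule()].
#' @export
itc_schedule_25C <- function() {
  injection_schedule(rep(2e-6, 20), syringe_conc = 1.84e-3,
                     cell_conc = 73e-6, temperature = 298.15)
}

#' @rdname itc_schedule_25C
#' @export
itc_schedule_37C <- function() {
  injection_schedule(rep(1.3e-6, 30), syringe_conc = 1.15e-3,
                     cell_conc = 48e-6, temperature = 310.15)
}

#' ITC thermogram container
#'
#' @param schedule An [injection_schedule()].
#' @param heats Normalized heats, kcal per mole of injectant, one per
#'   injection.
#' @return A `thermogram` object.
#' @export
thermogram <- function(schedule, heats) {
  stopifnot(inherits(schedule, "injection_schedule"))
  heats <- as.numeric(heats)
  if (length(heats) != length(schedule$injection_volumes))
    stop("thermogram: one heat per injection required")
  structure(list(schedule = schedule, heats = heats), class = "thermogram")
}

#' Cell composition after a given injection
#'
#' Standard perfusion-cell dilution bookkeeping: with cumulative injected
#' volume v and working volume V0,
#' `M = M0 * (1 - v/(2*V0)) / (1 + v/(2*V0))` and
#' `L = L_syr * (v/V0) / (1 + v/(2*V0))`.
#'
#' @param schedule An [injection_schedule()].
#' @param after_injection Injection index 0..n (0 = initial state).
#' @return Named numeric: `macromolecule`, `ligand_total` (molar).
#' @export
cell_concentrations <- function(schedule, after_injection) {
  stopifnot(inherits(schedule, "injection_schedule"))
  n <- length(schedule$injection_volumes)
  if (after_injection < 0 || after_injection > n)
    stop("cell_concentrations: index out of range 0..", n)
  v <- if (after_injection == 0) 0 else
    sum(schedule$injection_volumes[seq_len(after_injection)])
  r <- v / schedule$cell_volume
  c(macromolecule = schedule$cell_conc * (1 - r / 2) / (1 + r / 2),
    ligand_total = schedule$syringe_conc * r / (1 + r / 2))
}

## internal: composition at every injection index 1..n (vectorized)
.schedule_composition <- function(schedule) {
  v <- cumsum(schedule$injection_volumes)
  r <- v / schedule$cell_volume
  list(macromolecule = schedule$cell_conc * (1 - r / 2) / (1 + r / 2),
       ligand_total = schedule$syringe_conc * r / (1 + r / 2))
}

#' Cumulative heat, "set of identical sites" model
#'
#' Wiseman-style closed form: for n identical independent sites with
#' per-site KD, the per-site bound fraction is the quadratic root
#' `Theta = (1 + X/(nM) + kd/(nM) - sqrt((1 + X/(nM) + kd/(nM))^2 -
#' 4X/(nM))) / 2` and `Q = V0 * dh * n * M * Theta` (kcal).
#'
#' @param n_sites Stoichiometry n (> 0).
#' @param kd Average macroscopic dissociation constant (molar, > 0).
#' @param dh Binding enthalpy (kcal/mol).
#' @param macromolecule Current macromolecule concentration M (molar).
#' @param ligand_total Current total ligand X (molar); vectorized.
#' @param cell_volume V0 (liters).
#' @return Cumulative heat(s), kcal.
#' @export
total_heat_identical <- function(n_sites, kd, dh, macromolecule,
                                 ligand_total, cell_volume) {
  if (n_sites <= 0 || kd <= 0)
    stop("total_heat_identical: n_sites and kd must be > 0")
  nm <- n_sites * macromolecule
  a <- 1 + ligand_total / nm + kd / nm
  theta <- (a - sqrt(pmax(a^2 - 4 * ligand_total / nm, 0))) / 2
  cell_volume * dh * nm * theta
}

#' Cumulative heat, two interdependent non-equivalent sites
#'
#' Binding-polynomial model: free ligand L solves the mass balance
#' `L + M * nu(L) = X` with `nu` from `Z = 1 + K1 L + K1 K2 L^2`
#' (`K_i = 1/KD_i`), and
#' `Q = V0 * M * (dh1 * K1 L + (dh1 + dh2) * K1 K2 L^2) / Z`.
#'
#' @param kd1,kd2 Macroscopic stepwise dissociation constants (molar).
#' @param dh1,dh2 Stepwise binding enthalpies (kcal/mol).
#' @inheritParams total_heat_identical
#' @return Cumulative heat(s), kcal.
#' @export
total_heat_twosite <- function(kd1, kd2, dh1, dh2, macromolecule,
                               ligand_total, cell_volume) {
  L <- free_ligand(ligand_total, macromolecule, kd1, kd2)
  k1l <- L / kd1
  k12l2 <- k1l * L / kd2
  z <- 1 + k1l + k12l2
  cell_volume * macromolecule * (dh1 * k1l + (dh1 + dh2) * k12l2) / z
}

#' Per-injection normalized heats from a forward model
#'
#' Differential heat with the customary displaced-volume correction:
#' `q_i = [Q_i - Q_{i-1} + (dV_i/V0) * (Q_i + Q_{i-1})/2] /
#' (c_syr * dV_i) + heat_offset`, in kcal per mole of injectant.
#'
#' @param schedule An [injection_schedule()].
#' @param model_kind `"identical_sites"` or `"two_interdependent"`.
#' @param params Named list. Identical sites: `n_sites`, `kd`, `dh`,
#'   `heat_offset`. Two-site: `kd1`, `kd2`, `dh1`, `dh2`, `heat_offset`.
#' @return Numeric vector of per-injection heats (kcal/mol injectant).
#' @export
injection_heats <- function(schedule,
                            model_kind = c("identical_sites",
                                           "two_interdependent"),
                            params) {
  stopifnot(inherits(schedule, "injection_schedule"))
  model_kind <- match.arg(model_kind)
  comp <- .schedule_composition(schedule)
  v0 <- schedule$cell_volume
  offset <- if (is.null(params$heat_offset)) 0 else params$heat_offset
  Q <- switch(model_kind,
    identical_sites = total_heat_identical(
      params$n_sites, params$kd, params$dh,
      comp$macromolecule, comp$ligand_total, v0),
    two_interdependent = total_heat_twosite(
      params$kd1, params$kd2, params$dh1, params$dh2,
      comp$macromolecule, comp$ligand_total, v0))
  Qprev <- c(0, Q[-length(Q)])
  dv <- schedule$injection_volumes
  dq <- Q - Qprev + (dv / v0) * (Q + Qprev) / 2
  dq / (schedule$syringe_conc * dv) + offset
}

## internal: starting values from thermogram shape
.itc_specs <- function(model_kind, tg) {
  h <- tg$heats
  offset0 <- mean(tail(h, 3))
  dh0 <- h[1L] - offset0
  if (abs(dh0) < 0.5) dh0 <- sign(dh0 - 1e-9) * 1  # keep away from zero
  kd0 <- tg$schedule$cell_conc / 30
  kspec <- function(nm, init)
    param_spec(nm, init, lower = 1e-12, upper = 1e-1, log_scale = TRUE)
  if (model_kind == "identical_sites")
    list(param_spec("n_sites", 1.5, lower = 0.1, upper = 6),
         kspec("kd", kd0),
         param_spec("dh", dh0, lower = -100, upper = 100),
         param_spec("heat_offset", offset0, lower = -50, upper = 50))
  else
    list(kspec("kd1", kd0 / 3),
         kspec("kd2", kd0 * 3),
         param_spec("dh1", dh0 / 2, lower = -100, upper = 100),
         param_spec("dh2", dh0 / 2, lower = -100, upper = 100),
         param_spec("heat_offset", offset0, lower = -50, upper = 50))
}

#' Fit an ITC thermogram
#'
#' Fits per-injection normalized heats with either the "set of identical
#' sites" model (estimating stoichiometry n, average macroscopic KD and
#' dH) or the "two interdependent non-equivalent sites"
#' binding-polynomial model (estimating macroscopic stepwise KD,1/KD,2
#' and dH1/dH2); both include a constant dilution-heat offset.
#' Dissociation constants are fit in log10 space. For the two-site model
#' the cooperativity factor `y = 4 KD1/KD2` is attached.
#'
#' @param tg A [thermogram()].
#' @param model_kind `"identical_sites"` or `"two_interdependent"`.
#' @param drop_first_injection Discard injection 1 (customary for real
#'   instrument files where the first injection is unreliable)?
#' @param specs Optional [param_spec()] list overriding the defaults.
#' @param control See [fit_control()].
#' @return A `fit_result`; KD estimates are molar. Two-site fits carry
#'   `$cooperativity_y`.
#' @export
fit_itc <- function(tg,
                    model_kind = c("identical_sites", "two_interdependent"),
                    drop_first_injection = FALSE,
                    specs = NULL,
                    control = fit_control()) {
  stopifnot(inherits(tg, "thermogram"))
  model_kind <- match.arg(model_kind)
  keep <- seq_along(tg$heats)
  if (drop_first_injection) keep <- keep[-1L]
  if (length(keep) < 6)
    stop("fit_itc: need at least 6 informative injections")
  if (is.null(specs)) specs <- .itc_specs(model_kind, tg)
  model <- function(p, idx) {
    injection_heats(tg$schedule, model_kind, as.list(p))[idx]
  }
  fit <- nls_fit(model, keep, tg$heats[keep], specs, control = control)
  fit$model_kind <- model_kind
  if (model_kind == "two_interdependent" && fit$converged)
    fit$cooperativity_y <- cooperativity_factor(fit$estimates[["kd1"]],
                                                fit$estimates[["kd2"]])
  fit
}
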