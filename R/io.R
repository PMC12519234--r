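## CSV dialects. All file concentrations are micromolar (mM for the ITC
## syringe); internal representation is molar.

#' Read/write an equilibrium titration CSV
#'
#' Columns `ligand_conc_uM, signal`; the RNA concentration travels
#' separately (flag or argument) since it is constant per titration.
#'
#' @param path CSV path.
#' @param rna_uM RNA concentration in micromolar.
#' @param label Optional label.
#' @return An [equilibrium_titration()].
#' @export
read_titration_csv <- function(path, rna_uM, label = basename(path)) {
  d <- read.csv(path)
  need <- c("ligand_conc_uM", "signal")
  if (!all(need %in% names(d)))
    stop("read_titration_csv: need columns ", paste(need, collapse = ", "),
         " in ", path)
  equilibrium_titration(d$ligand_conc_uM * 1e-6, d$signal,
                        rna_uM * 1e-6, label = label)
}

#' @rdname read_titration_csv
#' @param curve An [equilibrium_titration()] to write.
#' @export
write_titration_csv <- function(curve, path) {
  write.csv(data.frame(ligand_conc_uM = curve$ligand_total * 1e6,
                       signal = curve$signal),
            path, row.names = FALSE)
  invisible(path)
}

#' Read/write a stopped-flow trace CSV
#'
#' Columns `time_s, signal`; ligand concentration via argument/flag.
#'
#' @param path CSV path.
#' @param ligand_uM Post-mix ligand concentration (micromolar).
#' @param rna_uM Post-mix RNA concentration (micromolar).
#' @return A [kinetic_trace()].
#' @export
read_trace_csv <- function(path, ligand_uM, rna_uM = 0.5) {
  d <- read.csv(path)
  need <- c("time_s", "signal")
  if (!all(need %in% names(d)))
    stop("read_trace_csv: need columns ", paste(need, collapse = ", "),
         " in ", path)
  suppressWarnings(kinetic_trace(d$time_s, d$signal,
                                 ligand_uM * 1e-6, rna_uM * 1e-6))
}

#' @rdname read_trace_csv
#' @param trace A [kinetic_trace()] to write.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(data.frame(time_s = trace$time_s, signal = trace$signal),
            path, row.names = FALSE)
  invisible(path)
}

#' Read/write a Job-plot CSV
#'
#' Either `x_fraction, delta_signal`, or `rna_uM, ligand_uM,
#' delta_signal` (converted to mole fractions internally).
#'
#' @param path CSV path.
#' @param total_uM Total concentration (micromolar); required for the
#'   `x_fraction` dialect, inferred for the concentration dialect.
#' @return A [job_series()].
#' @export
read_job_csv <- function(path, total_uM = NULL) {
  d <- read.csv(path)
  if (all(c("x_fraction", "delta_signal") %in% names(d))) {
    if (is.null(total_uM))
      stop("read_job_csv: total_uM is required with the x_fraction dialect")
    job_series(d$x_fraction, d$delta_signal, total_uM * 1e-6)
  } else if (all(c("rna_uM", "ligand_uM", "delta_signal") %in% names(d))) {
    tot <- d$rna_uM + d$ligand_uM
    if (diff(range(tot)) > 1e-6 * mean(tot))
      warning("read_job_csv: total concentration varies across rows")
    job_series(d$rna_uM / tot, d$delta_signal, mean(tot) * 1e-6)
  } else {
    stop("read_job_csv: need columns x_fraction,delta_signal or ",
         "rna_uM,ligand_uM,delta_signal in ", path)
  }
}

#' @rdname read_job_csv
#' @param series A [job_series()] to write.
#' @export
write_job_csv <- function(series, path) {
  write.csv(data.frame(x_fraction = series$mole_fraction_rna,
                       delta_signal = series$delta_signal),
            path, row.names = FALSE)
  invisible(path)
}

#' Read/write an ITC thermogram CSV
#'
#' Columns `injection_index, volume_uL, heat_kcal_per_mol`; schedule
#' concentrations via arguments/flags.
#'
#' @param path CSV path.
#' @param cell_uM Cell (RNA) concentration, micromolar.
#' @param syringe_mM Syringe (ligand) concentration, millimolar.
#' @param cell_volume_uL Working cell volume, microliters.
#' @param temperature Kelvin (metadata).
#' @return A [thermogram()].
#' @export
read_itc_csv <- function(path, cell_uM, syringe_mM, cell_volume_uL = 200,
                         temperature = 298.15) {
  d <- read.csv(path)
  need <- c("injection_index", "volume_uL", "heat_kcal_per_mol")
  if (!all(need %in% names(d)))
    stop("read_itc_csv: need columns ", paste(need, collapse = ", "),
         " in ", path)
  d <- d[order(d$injection_index), , drop = FALSE]
  sched <- injection_schedule(d$volume_uL * 1e-6,
                              syringe_conc = syringe_mM * 1e-3,
                              cell_conc = cell_uM * 1e-6,
                              cell_volume = cell_volume_uL * 1e-6,
                              temperature = temperature)
  thermogram(sched, d$heat_kcal_per_mol)
}

#' @rdname read_itc_csv
#' @param tg A [thermogram()] to write.
#' @export
write_itc_csv <- function(tg, path) {
  write.csv(data.frame(injection_index = seq_along(tg$heats),
                       volume_uL = tg$schedule$injection_volumes * 1e6,
                       heat_kcal_per_mol = tg$heats),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy qPCR Ct table CSV
#'
#' Columns `sample, condition, target, replicate, ct`.
#'
#' @param path CSV path.
#' @return data.frame suitable for [average_ct()]/[enrichment_table()].
#' @export
read_ct_csv <- function(path) {
  d <- read.csv(path)
  need <- c("sample", "condition", "target", "replicate", "ct")
  if (!all(need %in% names(d)))
    stop("read_ct_csv: need columns ", paste(need, collapse = ", "),
         " in ", path)
  d
}
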