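test_that("cell_concentrations follows the perfusion dilution convention", {
  sch <- itc_schedule_25C()
  c0 <- cell_concentrations(sch, 0)
  expect_equal(unname(c0["macromolecule"]), 73e-6)
  expect_equal(unname(c0["ligand_total"]), 0)
  # 10 x 2 uL into 200 uL: factors 0.95/1.05 and 0.1/1.05
  c10 <- cell_concentrations(sch, 10)
  expect_equal(unname(c10["macromolecule"]) / 73e-6, 0.95 / 1.05,
               tolerance = 1e-12)
  expect_equal(unname(c10["ligand_total"]) / 1.84e-3, 0.1 / 1.05,
               tolerance = 1e-12)
  expect_error(cell_concentrations(sch, 21), "range")
})

test_that("injection_schedule validates geometry", {
  expect_error(injection_schedule(rep(0, 5), 1e-3, 1e-5), "> 0")
  expect_error(injection_schedule(rep(30e-6, 10), 1e-3, 1e-5,
                                  cell_volume = 200e-6), "below the cell")
  expect_error(thermogram(itc_schedule_25C(), 1:5), "per injection")
})

test_that("total_heat_identical matches limits and the species oracle", {
  v0 <- 200e-6
  expect_equal(total_heat_identical(2, 1.5e-6, -10, 73e-6, 0, v0), 0)
  # kd -> 0, excess ligand: full saturation Q = V0*dh*n*M
  expect_equal(total_heat_identical(2, 1e-15, -10, 73e-6, 200e-6, v0),
               v0 * -10 * 2 * 73e-6, tolerance = 1e-6)
  # against the independent enumeration oracle
  for (x in c(20e-6, 73e-6, 150e-6, 300e-6)) {
    expect_equal(total_heat_identical(2, 1.5e-6, -10, 73e-6, x, v0),
                 oracle_identical_heat(2, 1.5e-6, -10, 73e-6, x, v0),
                 tolerance = 1e-6)
  }
})

test_that("total_heat_twosite limits and statistical equivalence", {
  v0 <- 200e-6
  expect_equal(total_heat_twosite(0.65e-6, 3.12e-6, -8, -12, 48e-6, 0, v0), 0)
  # kd2 -> infinity: reduces to single-site with n = 1
  expect_equal(total_heat_twosite(1e-6, 1e9, -8, -12, 48e-6, 60e-6, v0),
               total_heat_identical(1, 1e-6, -8, 48e-6, 60e-6, v0),
               tolerance = 1e-8)
  # saturation: Q -> V0*M*(dh1 + dh2)
  expect_equal(total_heat_twosite(1e-9, 4e-9, -8, -12, 48e-6, 5e-3, v0),
               v0 * 48e-6 * (-20), tolerance = 1e-4)
  # y = 1 statistical identity: kd1 = k/2, kd2 = 2k, dh split evenly
  k <- 1.5e-6
  for (x in c(10e-6, 50e-6, 120e-6, 400e-6)) {
    expect_equal(total_heat_twosite(k / 2, 2 * k, -5, -5, 73e-6, x, v0),
                 total_heat_identical(2, k, -5, 73e-6, x, v0),
                 tolerance = 1e-8)
  }
})

test_that("injection heats: offsets, saturation tail, heat conservation", {
  sch <- itc_schedule_25C()
  # zero enthalpy -> constant offset
  q0 <- injection_heats(sch, "identical_sites",
                        list(n_sites = 2, kd = 1.5e-6, dh = 0,
                             heat_offset = 0.35))
  expect_equal(q0, rep(0.35, 20))
  # far-past-saturation tail approaches the offset
  p <- list(n_sites = 2, kd = 1.5e-6, dh = -10, heat_offset = 0.1)
  q <- injection_heats(sch, "identical_sites", p)
  expect_lt(abs(q[20] - 0.1), 0.01 * 10)
  # cumulative dilution-corrected heats match the closed-form Q within 0.5%
  comp <- cell_concentrations(sch, 20)
  Qfinal <- total_heat_identical(2, 1.5e-6, -10,
                                 comp["macromolecule"],
                                 comp["ligand_total"], sch$cell_volume)
  dv <- sch$injection_volumes
  raw <- (q - 0.1) * sch$syringe_conc * dv     # kcal per injection
  # undo the displaced-volume correction cumulatively
  Qs <- 0
  for (i in seq_along(raw)) {
    Qs <- c(Qs, (raw[i] + Qs[i] * (1 - dv[i] / (2 * sch$cell_volume))) /
                (1 + dv[i] / (2 * sch$cell_volume)))
  }
  expect_equal(unname(Qs[21]), unname(Qfinal), tolerance = 5e-3)
})

test_that("two-site injection model conserves mass balance per injection", {
  sch <- itc_schedule_37C()
  p <- list(kd1 = 0.65e-6, kd2 = 3.12e-6, dh1 = -8, dh2 = -12,
            heat_offset = 0)
  for (i in c(1, 10, 20, 30)) {
    comp <- cell_concentrations(sch, i)
    lf <- free_ligand(comp["ligand_total"], comp["macromolecule"],
                      p$kd1, p$kd2)
    resid <- lf + comp["macromolecule"] *
      twosite_occupancy(p$kd1, p$kd2, lf) - comp["ligand_total"]
    expect_lt(abs(resid) / comp["ligand_total"], 1e-10)
  }
})

test_that("identical-sites sigmoid inflects near molar ratio n", {
  # noise-free steep simulation (c = n*M/kd >> 1): steepest heat change
  # falls where the molar ratio crosses the stoichiometry
  sch <- itc_schedule_25C()
  q <- injection_heats(sch, "identical_sites",
                       list(n_sites = 2, kd = 0.2e-6, dh = -10,
                            heat_offset = 0))
  steep <- which.max(abs(diff(q)))
  comp <- sapply(1:20, function(i) cell_concentrations(sch, i))
  ratio <- comp["ligand_total", ] / comp["macromolecule", ]
  expect_equal(mean(ratio[steep + 0:1]), 2, tolerance = 0.15)
})

test_that("fit_itc round-trips noise-free thermograms", {
  tg <- gen_itc("identical_sites",
                list(n_sites = 2, kd = 1.5e-6, dh = -10, heat_offset = 0))
  fit <- fit_itc(tg, "identical_sites")
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates[["n_sites"]]), 2, tolerance = 5e-3)
  expect_equal(unname(fit$estimates[["kd"]]), 1.5e-6, tolerance = 5e-3)
  expect_equal(unname(fit$estimates[["dh"]]), -10, tolerance = 5e-3)

  tg2 <- gen_itc("two_interdependent",
                 list(kd1 = 0.65e-6, kd2 = 3.12e-6, dh1 = -8, dh2 = -12,
                      heat_offset = 0))
  fit2 <- fit_itc(tg2, "two_interdependent")
  expect_true(fit2$converged)
  expect_equal(unname(fit2$estimates[["kd1"]]), 0.65e-6, tolerance = 1e-2)
  expect_equal(unname(fit2$estimates[["kd2"]]), 3.12e-6, tolerance = 1e-2)
  expect_equal(round(fit2$cooperativity_y, 1), 0.8)
})

test_that("degenerate thermogram of pure offset is flagged via dh ~ 0", {
  sch <- itc_schedule_25C()
  tg <- thermogram(sch, rep(0.2, 20))
  fit <- fit_itc(tg, "identical_sites")
  expect_true(!fit$converged || abs(fit$estimates[["dh"]]) < 0.05)
})

test_that("drop_first_injection removes one point from the fit", {
  tg <- gen_itc("identical_sites",
                list(n_sites = 2, kd = 1.5e-6, dh = -10, heat_offset = 0))
  fit <- fit_itc(tg, "identical_sites", drop_first_injection = TRUE)
  expect_equal(fit$n_points, 19)
  expect_equal(unname(fit$estimates[["kd"]]), 1.5e-6, tolerance = 1e-2)
})
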