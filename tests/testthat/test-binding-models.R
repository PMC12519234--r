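test_that("quadratic_fraction_bound matches the mass-balance oracle", {
  # trivial limits
  expect_equal(quadratic_fraction_bound(1e-6, 0.5e-6, 0), 0)
  expect_equal(quadratic_fraction_bound(1e-12, 0.5e-6, 45e-6), 1,
               tolerance = 1e-6)
  # frozen value cross-checked against bisection on L*(R-B)/B = KD
  expect_equal(quadratic_fraction_bound(0.62e-6, 0.5e-6, 45e-6), 0.9863,
               tolerance = 1e-4)
  # property: 1000 random triples against the independent oracle
  set.seed(99)
  for (i in 1:1000) {
    kd <- 10^runif(1, -9, -4)
    r <- 10^runif(1, -8, -5)
    l <- 10^runif(1, -9, -4)
    expect_equal(quadratic_fraction_bound(kd, r, l),
                 oracle_fraction_bound(kd, r, l), tolerance = 1e-8)
  }
  expect_error(quadratic_fraction_bound(-1e-6, 1e-6, 1e-6), "nonnegative")
})

test_that("hill_signal half-saturates at kd_av and reduces to Langmuir", {
  expect_equal(hill_signal(0.96e-6, 0.96e-6, 2, 1), 0.5)
  L <- titration_ligand_series()
  expect_equal(hill_signal(L, 1e-6, 1, 0.8), 0.8 * L / (1e-6 + L))
  # frozen direct evaluation
  expect_equal(hill_signal(2e-6, 0.96e-6, 2, 1), 0.8128, tolerance = 1e-4)
  expect_error(hill_signal(1e-6, -1, 2), "> 0")
})

test_that("twosite_occupancy limits, frozen value, and species oracle", {
  expect_equal(twosite_occupancy(0.5e-6, 2.2e-6, 0), 0)
  expect_equal(twosite_occupancy(0.5e-6, 2.2e-6, 1), 2, tolerance = 1e-5)
  expect_equal(twosite_occupancy(0.5e-6, 2.2e-6, 1e-6), 0.9767,
               tolerance = 1e-4)
  # cross-check by species enumeration at matched free ligand
  sp <- oracle_twosite_species(0.5e-6, 2.2e-6, 1e-6, 3e-6)
  nu <- twosite_occupancy(0.5e-6, 2.2e-6, sp$free)
  expect_equal(nu * 1e-6, sp$bound_ligand, tolerance = 1e-10)
  expect_error(twosite_occupancy(0, 1e-6, 1e-6), "> 0")
})

test_that("y = 1 statistical limit equals independent identical sites", {
  # kd1 = k/2, kd2 = 2k (y = 1) must equal 2L/(k+L) exactly
  k <- 1.3e-6
  L <- c(0, 10^seq(-8, -4, length.out = 30))
  expect_equal(twosite_occupancy(k / 2, 2 * k, L), 2 * L / (k + L),
               tolerance = 1e-12)
  expect_equal(cooperativity_factor(k / 2, 2 * k), 1)
})

test_that("twosite_signal saturates at amplitude and degrades gracefully", {
  expect_equal(twosite_signal(1, 0.5e-6, 2.2e-6, 1), 1, tolerance = 1e-5)
  expect_equal(twosite_signal(1e-6, 0.5e-6, 2.2e-6, 1), 0.4884,
               tolerance = 1e-4)
  # second site never fills: reduces to a single-site hyperbola at d/2
  L <- 10^seq(-8, -4, length.out = 20)
  expect_equal(twosite_signal(L, 1e-6, 1e9, 1), 0.5 * L / (1e-6 + L),
               tolerance = 1e-10)
})

test_that("free_ligand satisfies mass balance", {
  expect_equal(free_ligand(1e-6, 0, 1e-6, 1e-6), 1e-6)
  expect_equal(free_ligand(1e-6, 0.5e-6, 1e3, 1e3), 1e-6, tolerance = 1e-6)
  # all ligand sequestered when 2R >= Ltot and binding is infinitely tight
  # (exact root is sqrt(R*kd1/ ~1) scale, ~2e-11 at kd = 1e-15)
  expect_lt(free_ligand(1e-6, 0.5e-6, 1e-15, 1e-15), 1e-9)
  # property: mass balance to 1e-10 relative over random regimes
  set.seed(5)
  for (i in 1:200) {
    kd1 <- 10^runif(1, -8, -5); kd2 <- 10^runif(1, -8, -5)
    r <- 10^runif(1, -7, -4); lt <- 10^runif(1, -7, -3)
    lf <- free_ligand(lt, r, kd1, kd2)
    resid <- lf + r * twosite_occupancy(kd1, kd2, lf) - lt
    expect_lt(abs(resid) / lt, 1e-10)
  }
})

test_that("cooperativity_factor matches its definition and printed rounding", {
  expect_equal(cooperativity_factor(1e-6, 4e-6), 1)
  expect_equal(cooperativity_factor(1e-6, 1e-6), 4)
  expect_equal(round(cooperativity_factor(0.65e-6, 3.12e-6), 1), 0.8)
  expect_error(cooperativity_factor(0, 1e-6), "> 0")
})

test_that("model signals are monotone non-decreasing in ligand", {
  L <- sort(10^runif(50, -9, -4))
  expect_true(all(diff(quadratic_fraction_bound(0.62e-6, 0.5e-6, L)) >= 0))
  expect_true(all(diff(hill_signal(L, 0.96e-6, 2, 1)) >= 0))
  expect_true(all(diff(twosite_signal(L, 0.5e-6, 2.2e-6, 1)) >= 0))
})

test_that("normalize_titration maps endpoints to 0 and 1", {
  expect_equal(normalize_titration(c(10, 7, 4)), c(0, 0.5, 1))
  expect_error(normalize_titration(c(3, 5, 3)), "degenerate")
  set.seed(2)
  raw <- cumsum(rnorm(10))
  if (raw[10] == raw[1]) raw[10] <- raw[10] + 1
  z <- normalize_titration(raw)
  expect_equal(z[1], 0)
  expect_equal(z[10], 1)
  expect_warning(normalize_titration(c(10, 4), direction = "increase"),
                 "decreases")
})

test_that("equilibrium_titration validates its invariants", {
  expect_error(equilibrium_titration(c(0, 1, 2) * 1e-6, c(0, 1, 2), 1e-6),
               "at least 4")
  expect_error(equilibrium_titration(c(0, 2, 1, 3) * 1e-6, rep(0, 4), 1e-6),
               "non-decreasing")
  expect_error(equilibrium_titration(c(0, 1, 2, 3) * 1e-6, rep(0, 4), 0),
               "rna_total")
})

test_that("fit_titration round-trips noise-free curves", {
  # single site, KD = 0.62 uM: recovered within 0.1%
  cv <- gen_titration("quadratic_single_site", list(kd = 0.62e-6))
  fit <- fit_titration(cv, "quadratic_single_site")
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates[["kd"]]), 0.62e-6, tolerance = 1e-3)

  # two-site, 0.5/2.2 uM: both within 1%, cooperativity factor attached
  cv2 <- gen_titration("two_site", list(kd1 = 0.5e-6, kd2 = 2.2e-6))
  fit2 <- fit_titration(cv2, "two_site")
  expect_true(fit2$converged)
  expect_equal(unname(fit2$estimates[["kd1"]]), 0.5e-6, tolerance = 1e-2)
  expect_equal(unname(fit2$estimates[["kd2"]]), 2.2e-6, tolerance = 1e-2)
  expect_equal(fit2$cooperativity_y,
               cooperativity_factor(fit2$estimates[["kd1"]],
                                    fit2$estimates[["kd2"]]))

  # Hill round trip
  cv3 <- gen_titration("hill", list(kd_av = 0.96e-6, hill_n = 2))
  fit3 <- fit_titration(cv3, "hill")
  expect_equal(unname(fit3$estimates[["kd_av"]]), 0.96e-6, tolerance = 1e-3)
  expect_equal(unname(fit3$estimates[["hill_n"]]), 2, tolerance = 1e-3)
})

test_that("constant signal yields a degenerate fit, not an error", {
  cv <- equilibrium_titration(titration_ligand_series(),
                              rep(0.5, 14), 0.5e-6)
  fit <- fit_titration(cv, "quadratic_single_site")
  expect_true(!fit$converged || abs(fit$estimates[["amplitude"]]) < 1e-3)
})

test_that("free-ligand mode changes the two-site fit only slightly at 0.5 uM RNA", {
  cv <- gen_titration("two_site", list(kd1 = 0.5e-6, kd2 = 2.2e-6))
  f_tot <- fit_titration(cv, "two_site")
  f_free <- fit_titration(cv, "two_site", free_ligand_mode = TRUE)
  expect_true(f_free$converged)
  # data generated with the total-ligand convention; the exact-free-ligand
  # model compensates with a smaller first KD (free L < total L at the
  # low-concentration points where 0.5 uM RNA depletes the ligand)
  expect_lt(f_free$estimates[["kd1"]], f_tot$estimates[["kd1"]])
  expect_lt(abs(log(f_free$estimates[["kd1"]] / f_tot$estimates[["kd1"]])),
            log(10))
})
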