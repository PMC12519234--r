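# Independent oracles used to check closed-form model code. These solve
# the mass-balance equations by brute-force bisection on species
# concentrations and never call the package's model functions.

# Single-site mass balance: find bound complex B such that
# (R - B) * (L - B) / B = KD, return bound fraction B / R.
oracle_fraction_bound <- function(kd, r, l) {
  if (l == 0 || r == 0) return(0)
  f <- function(b) (r - b) * (l - b) - kd * b
  b <- uniroot(f, c(0, min(r, l)), tol = 1e-15)$root
  for (i in 1:3)  # Newton polish to machine precision
    b <- b - f(b) / (-(l - b) - (r - b) - kd)
  b / r
}

# Two-site species enumeration: given totals and stepwise KDs, bisect on
# free ligand and return all species concentrations.
oracle_twosite_species <- function(kd1, kd2, r_tot, l_tot) {
  bal <- function(lf) {
    z <- 1 + lf / kd1 + lf^2 / (kd1 * kd2)
    r <- r_tot / z
    rl <- r * lf / kd1
    rl2 <- rl * lf / kd2
    lf + rl + 2 * rl2 - l_tot
  }
  lf <- if (l_tot == 0) 0 else uniroot(bal, c(0, l_tot), tol = 1e-18)$root
  z <- 1 + lf / kd1 + lf^2 / (kd1 * kd2)
  r <- r_tot / z
  rl <- r * lf / kd1
  rl2 <- rl * lf / kd2
  list(free = lf, r = r, rl = rl, rl2 = rl2,
       bound_ligand = rl + 2 * rl2)
}

# Identical-sites heat content by species enumeration: n independent
# sites of per-site dissociation constant kd on M molar macromolecule.
oracle_identical_heat <- function(n, kd, dh, m, x, v0) {
  sites <- n * m
  bal <- function(lf) lf + sites * lf / (kd + lf) - x
  lf <- if (x == 0) 0 else uniroot(bal, c(0, x), tol = 1e-18)$root
  bound <- sites * lf / (kd + lf)
  v0 * dh * bound
}
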