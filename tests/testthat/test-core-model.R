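test_that("Gibbs-Helmholtz propagation returns the reference value at reference conditions", {
  m <- model_22gt()
  expect_equal(gibbs_energy(m$transitions[[1]], 298.15, 0.1), -4.7,
               tolerance = 1e-12)
  expect_equal(gibbs_energy(m$transitions[[2]], 298.15, 0.1), -1.0,
               tolerance = 1e-12)
  expect_equal(gibbs_energy(m$sites[[1]], 298.15), -9.6, tolerance = 1e-12)
  # dCp = 0 and dH = dG: temperature drops out entirely
  t0 <- transition_thermo("U->I", -3, -3, 0, 0)
  for (T in c(280, 298.15, 350)) {
    expect_equal(gibbs_energy(t0, T, 0.1), -3)
  }
})

test_that("potassium linkage shifts folding energies as n R T log(cK/cref)", {
  m <- model_22gt()
  # frozen hand evaluations of the closed form (Table-derived records)
  expect_equal(gibbs_energy(m$transitions[[1]], 298.15, 0.001), -1.152965,
               tolerance = 1e-5)
  expect_equal(gibbs_energy(m$transitions[[1]], 293.15, 0.001), -1.694537,
               tolerance = 1e-5)
  expect_equal(gibbs_energy(m$transitions[[2]], 293.15, 0.001), -0.274863,
               tolerance = 1e-5)
  # sites carry no salt term
  expect_identical(gibbs_energy(m$sites[[2]], 310), gibbs_energy(m$sites[[2]], 310))
})

test_that("domain errors name the offending field", {
  m <- model_22gt()
  expect_error(gibbs_energy(m$transitions[[1]], -1, 0.1), "T")
  expect_error(gibbs_energy(m$transitions[[1]], 298.15, 0), "cK")
  expect_error(conditions(200, 0.1), "T")
  expect_error(conditions(298.15, -0.1), "cK")
})

test_that("equilibrium constants match direct exponentiation and affinity range", {
  expect_identical(equilibrium_constant(0, 298.15), 1)
  expect_equal(equilibrium_constant(-9.6, 298.15), exp(9.6 / (1.9872e-3 * 298.15)))
  expect_equal(equilibrium_constant(-9.6, 298.15) / 1.09e7, 1, tolerance = 0.01)
  expect_equal(equilibrium_constant(-8.7, 298.15) / 2.38e6, 1, tolerance = 0.01)
  expect_gt(equilibrium_constant(-5, 300), equilibrium_constant(-4, 300))
})

test_that("species enthalpies are path sums from U and path-independent", {
  m <- model_22gt()
  H <- species_enthalpies(m, 298.15)
  expect_identical(H[["U"]], 0)
  expect_identical(H[["I"]], -34)
  expect_identical(H[["Q"]], -56)
  expect_identical(H[["LIL"]], -34 - 18 - 20)
  # LIL via IL (site2 then site1) equals LIL via LI (site1 then site2)
  viaIL <- H[["IL"]] + (H[["LI"]] - H[["I"]])
  viaLI <- H[["LI"]] + (H[["IL"]] - H[["I"]])
  expect_identical(viaIL, viaLI)
  # all dCp zero: enthalpies independent of temperature
  m0 <- system_model(
    list(transition_thermo("U->I", -4.7, -34, 0, -1.3),
         transition_thermo("I->Q", -1, -22, 0, -0.4)),
    list(site_thermo(1, -9.6, -18, 0), site_thermo(2, -8.7, -20, 0)))
  expect_identical(species_enthalpies(m0, 280), species_enthalpies(m0, 360))
})

test_that("Hess additivity: the composite U->Q step equals the sum of its parts", {
  m <- model_22gt()
  composite <- transition_thermo("I->Q", -5.7, -56, -0.32, -1.7)
  set.seed(1)
  for (i in 1:20) {
    T <- runif(1, 275, 375); cK <- 10^runif(1, -4, -1)
    expect_equal(gibbs_energy(m$transitions[[1]], T, cK) +
                   gibbs_energy(m$transitions[[2]], T, cK),
                 gibbs_energy(composite, T, cK), tolerance = 1e-12)
    expect_equal(step_enthalpy(m$transitions[[1]], T) +
                   step_enthalpy(m$transitions[[2]], T),
                 step_enthalpy(composite, T), tolerance = 1e-12)
  }
})

test_that("linkage identity: d(dG)/d(log cK) equals n R T", {
  m <- model_22gt()
  for (tr in m$transitions) {
    for (T in c(283.15, 298.15, 330)) {
      cK <- 0.01; h <- 1e-6
      num <- (gibbs_energy(tr, T, cK * exp(h)) -
                gibbs_energy(tr, T, cK * exp(-h))) / (2 * h)
      expect_equal(num, tr$n * gas_constant() * T, tolerance = 1e-6)
    }
  }
})

test_that("van't Hoff identity: -R dlnK/d(1/T) recovers the propagated enthalpy", {
  tr <- transition_thermo("U->I", -4.7, -34, -0.22, -1.3)
  for (T in c(285, 298.15, 340)) {
    h <- 1e-8
    invT <- 1 / T
    lnK <- function(it) -gibbs_energy(tr, 1 / it, 0.1) / (gas_constant() / it)
    num <- -gas_constant() * (lnK(invT + h) - lnK(invT - h)) / (2 * h)
    expect_equal(num, step_enthalpy(tr, T), tolerance = 1e-4)
  }
})

test_that("ligand-free speciation matches the closed-form three-state weights", {
  m <- model_22gt()
  sp <- solve_speciation(m, conditions(298.15, 0.1, 10e-6, 0))
  RT <- gas_constant() * 298.15
  kUI <- exp(4.7 / RT); kIQ <- exp(1.0 / RT)
  z <- 1 + kUI + kUI * kIQ
  expect_equal(sp$fractions[["U"]], 1 / z, tolerance = 1e-12)
  expect_equal(sp$fractions[["I"]], kUI / z, tolerance = 1e-12)
  expect_equal(sp$fractions[["Q"]], kUI * kIQ / z, tolerance = 1e-12)
  expect_equal(unname(sp$fractions[c("U", "I", "Q")]),
               c(5.6e-5, 0.156, 0.844), tolerance = 5e-3)
  expect_true(all(sp$fractions[c("QL", "IL", "LI", "LIL")] == 0))
  expect_identical(sp$freeLigand, 0)
})

test_that("the Q form dominates 60/40 over I at 20 degC and 1 mM K+", {
  m <- model_22gt()
  sp <- solve_speciation(m, conditions(celsius_to_kelvin(20), 1e-3, 10e-6, 0))
  expect_equal(sp$fractions[["Q"]], 0.6, tolerance = 0.05)
  expect_equal(sp$fractions[["I"]], 0.4, tolerance = 0.08)
})

test_that("disabling binding zeroes all complexes and leaves the ligand free", {
  m <- no_binding_model()
  sp <- solve_speciation(m, conditions(310, 0.1, 10e-6, 25e-6))
  expect_lt(sum(sp$fractions[c("QL", "IL", "LI", "LIL")]), 1e-10)
  expect_equal(sp$freeLigand, 25e-6, tolerance = 1e-8)
})

test_that("speciation satisfies the mass-action relations and both balances", {
  m <- model_22gt()
  set.seed(42)
  for (i in 1:25) {
    cond <- random_condition()
    sp <- solve_speciation(m, cond)
    f <- sp$fractions; L <- sp$freeLigand
    RT <- gas_constant() * cond$T
    K1 <- equilibrium_constant(gibbs_energy(m$sites[[1]], cond$T), cond$T)
    K2 <- equilibrium_constant(gibbs_energy(m$sites[[2]], cond$T), cond$T)
    expect_equal(sum(f), 1, tolerance = 1e-9)
    expect_equal(f[["QL"]], K2 * f[["Q"]] * L, tolerance = 1e-8)
    expect_equal(f[["IL"]], K2 * f[["I"]] * L, tolerance = 1e-8)
    expect_equal(f[["LI"]], K1 * f[["I"]] * L, tolerance = 1e-8)
    expect_equal(f[["LIL"]], K1 * K2 * f[["I"]] * L * L, tolerance = 1e-8)
    bound <- cond$cDNA * sum(f * c(0, 0, 0, 1, 1, 1, 2))
    expect_equal(L + bound, cond$cL, tolerance = 1e-8 * cond$cL)
    # thermodynamic cycle: the two routes to LIL agree
    expect_equal(f[["LI"]] * K2 * L, f[["IL"]] * K1 * L, tolerance = 1e-12)
  }
})

test_that("fractions sum to one across a large random condition sweep", {
  m <- model_22gt()
  set.seed(7)
  n <- 1e4
  Tv <- runif(n, 274, 379)
  cKv <- 10^runif(n, -4, -1)
  cDNAv <- 10^runif(n, -6.5, -4)
  cLv <- 10^runif(n, -7, -4.3)
  sg <- quadlink:::speciation_grid(m, Tv, cKv, cDNAv, cLv)
  expect_true(all(abs(rowSums(sg$fractions) - 1) < 1e-9))
  expect_true(all(sg$fractions >= 0 & sg$fractions <= 1))
  expect_true(all(sg$freeLigand >= 0 & sg$freeLigand <= cLv))
})

test_that("speciation matches the free-energy-minimization oracle on 100 random instances", {
  m <- model_22gt()
  set.seed(5)
  worst <- 0
  for (i in 1:100) {
    cond <- random_condition()
    a <- solve_speciation(m, cond)
    b <- oracle_speciation(m, cond)
    worst <- max(worst, max(abs(a$fractions - b$fractions)))
  }
  expect_lt(worst, 1e-6)
})
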