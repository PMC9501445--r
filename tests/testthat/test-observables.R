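test_that("normalized CD signal follows alphaI fI + alphaU", {
  expect_identical(cd_normalized(0, 0, 0.5), 0)   # pure Q
  expect_identical(cd_normalized(0, 1, 0.5), 1)   # pure U
  expect_equal(cd_normalized(0.4, 0.0125, 0.5), 0.2125)
  # bounded within [0, 1] for valid fractions and fI in [0, 1]
  set.seed(2)
  aI <- runif(50); aU <- runif(50) * (1 - aI); fI <- runif(50)
  f <- cd_normalized(aI, aU, fI)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("baseline denormalization inverts normalization exactly", {
  tempC <- seq(5, 95, by = 5)
  bQ <- c(2.1e5, -150); bU <- c(3.5e4, -80)
  expect_equal(cd_denormalize(0, tempC, bQ, bU), bQ[1] + bQ[2] * tempC)
  expect_equal(cd_denormalize(1, tempC, bQ, bU), bU[1] + bU[2] * tempC)
  set.seed(3)
  f <- runif(length(tempC))
  round_trip <- cd_normalize_raw(cd_denormalize(f, tempC, bQ, bU), tempC, bQ, bU)
  expect_equal(round_trip, f, tolerance = 1e-12)
  # equal baselines on the grid are degenerate
  expect_error(cd_denormalize(f, tempC, c(1, 0), c(1, 0)), "degenerate")
})

test_that("model excess heat capacity integrates to the total enthalpy change", {
  m <- model_22gt()
  for (cK in c(0.001, 0.1)) {
    tc <- seq(0.5, 95, by = 0.1)
    cp <- dsc_excess_cp(m, tc, cK)
    area <- sum(diff(tc) * (head(cp, -1) + tail(cp, -1)) / 2)
    dh <- mean_excess_enthalpy(m, celsius_to_kelvin(range(tc)), cK)
    expect_equal(area, dh[2] - dh[1], tolerance = 0.01 * abs(dh[2] - dh[1]))
  }
  # zero enthalpies give an identically zero excess curve
  m0 <- system_model(
    list(transition_thermo("U->I", -4.7, 0, 0, 0),
         transition_thermo("I->Q", -1, 0, 0, 0)),
    list(site_thermo(1, -9.6, 0, 0), site_thermo(2, -8.7, 0, 0)))
  expect_true(all(abs(dsc_excess_cp(m0, seq(10, 90, 1), 0.1)) < 1e-9))
  expect_warning(dsc_excess_cp(m, seq(10, 90, 5), 0.1, step = 2), "step")
})

test_that("two-state limit reproduces the analytic van't Hoff peak height", {
  dH <- -60; dG <- -5.7
  m2 <- two_state_model(dG, dH)
  Tm <- 298.15 * dH / (dH - dG)     # where the composite dG(T) crosses zero
  tc <- seq(20, 90, by = 0.02)
  cp <- dsc_excess_cp(m2, tc, 0.1, step = 0.02)
  expect_equal(max(cp), vant_hoff_peak(dH, Tm), tolerance = 0.005)
})

test_that("intrinsic-baseline fitting recovers a known quadratic under a peak", {
  tc <- seq(0.5, 95, by = 0.5)
  quad <- c(1.3, 6e-3, -1.5e-5)
  base <- quad[1] + quad[2] * tc + quad[3] * tc^2
  peak <- 3 * exp(-((tc - 55) / 6)^2)
  fit <- dsc_intrinsic_baseline(tc, base + peak)
  expect_equal(fit$coef, quad, tolerance = 1e-6)
  expect_equal(fit$excess, peak, tolerance = 1e-6)
  # exactly quadratic thermogram: excess is identically zero
  fit0 <- dsc_intrinsic_baseline(tc, base)
  expect_true(all(abs(fit0$excess) < 1e-10))
  # windows overlapping the transition bias the baseline
  fitBad <- dsc_intrinsic_baseline(tc, base + peak,
                                   lowWindow = c(30, 50), highWindow = c(55, 75))
  expect_gt(max(abs(fitBad$coef - quad)), 1e-3)
  expect_error(dsc_intrinsic_baseline(tc, base, lowWindow = c(-10, -5)),
               "low-temperature")
})

test_that("ITC heats vanish when binding is off and DNA is already folded", {
  m <- no_binding_model()
  h <- itc_heats(m, itc_protocol(tempC = 5.1), dilutionOffset = 0)
  expect_true(all(abs(h) < 1e-9))
  h2 <- itc_heats(m, itc_protocol(tempC = 5.1), dilutionOffset = -0.4)
  expect_equal(h2, rep(-0.4, 25), tolerance = 1e-9)
})

test_that("first-injection heat approaches the saturation-limit path enthalpy", {
  # strong binding, large ligand excess: every injected strand ends as LIL
  m <- system_model(
    model_22gt()$transitions,
    list(site_thermo(1, -14, -18, 0), site_thermo(2, -14, -20, 0)))
  proto <- itc_protocol(tempC = 25, cellLigand = 50e-6,
                        injectionVolumes = rep(2e-6, 3))
  h <- itc_heats(m, proto)
  H <- species_enthalpies(m, 298.15)
  syr <- solve_speciation(m, conditions(298.15, 0.1, 70e-6, 0))
  expected <- H[["LIL"]] - sum(syr$fractions * H)
  expect_equal(h[1], unname(expected), tolerance = 0.02 * abs(expected))
})

test_that("cumulative ITC heat equals the cell enthalpy inventory change", {
  m <- model_22gt()
  proto <- itc_protocol(tempC = 25)
  h <- itc_heats(m, proto)
  V0 <- proto$cellVolume
  H <- species_enthalpies(m, 298.15)
  hvol <- function(cDNA, cL) {
    sp <- solve_speciation(m, conditions(298.15, proto$cK, cDNA, cL))
    cDNA * sum(sp$fractions * H)
  }
  # replay the displacement bookkeeping independently, injection by injection
  cDNA <- 0; cL <- proto$cellLigand
  hSyr <- hvol(proto$syringeDNA, 0)
  total <- 0
  for (v in proto$injectionVolumes) {
    hBefore <- hvol(cDNA, cL)
    cDNA <- cDNA * (1 - v / V0) + proto$syringeDNA * v / V0
    cL <- cL * (1 - v / V0)
    total <- total + (V0 * hvol(cDNA, cL) - (V0 - v) * hBefore - v * hSyr)
  }
  expect_equal(sum(h * proto$injectionVolumes * proto$syringeDNA), total,
               tolerance = 1e-6)
})

test_that("intermediate-spectrum estimation is exact on noiseless data and bounded under noise", {
  sc <- scenario_spec(seed = 9)
  sm <- make_cd(sc)$spectra
  tr <- sm$truth
  est0 <- estimate_intermediate_spectrum(tr$noiseless, tr$fractions,
                                         tr$basis[, "Q"], tr$basis[, "U"])
  expect_equal(est0$spectrumI, unname(tr$basis[, "I"]), tolerance = 1e-8)
  est <- estimate_intermediate_spectrum(sm$data, tr$fractions,
                                        tr$basis[, "Q"], tr$basis[, "U"])
  # per-wavelength error within 3 standard errors of the weighted estimator
  se <- tr$sigma / sqrt(sum(tr$fractions[, "I"]^2))
  expect_true(all(abs(est$spectrumI - tr$basis[, "I"]) < 3.5 * se))
  # intermediate never populated: unidentifiable
  frQ <- tr$fractions; frQ[, "I"] <- 0; frQ[, "Q"] <- 1 - frQ[, "U"]
  expect_error(estimate_intermediate_spectrum(tr$noiseless, frQ,
                                              tr$basis[, "Q"], tr$basis[, "U"]),
               "unidentifiable")
})

test_that("nearest-neighbor extinction reproduces reference values", {
  expect_equal(nn_extinction("GGGTTAGGGTTAGGGTTAGGGT"), 223500)
  # a dinucleotide has no internal-monomer correction
  expect_equal(nn_extinction("AT"), 22800)
  expect_equal(nn_extinction("at"), 22800)
  # reversal changes epsilon only through dinucleotide order
  expect_equal(nn_extinction("AAGT") - nn_extinction("TGAA"),
               (27400 + 25000 + 20000) - (19000 + 25200 + 27400))
  expect_error(nn_extinction("ACGX"), "position 4")
  expect_error(nn_extinction("A"), "at least 2")
})
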