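# Seeded synthetic datasets with the statistical structure the analysis
# assumes: smooth instrument baselines plus white Gaussian measurement
# noise, under the published 22GT/360A parameter set by default.

#' Synthetic experiment scenario
#'
#' Defines the simulated study: the true model, the experiment menus
#' (DSC and CD at K+ levels 1, 10 and 100 mM; temperature-series spectra
#' at 10 mM; reverse ITC at 15, 25 and 40 degC), instrument baselines and
#' per-experiment noise.  Defaults emulate the study conditions: DSC scans
#' 0.5-95 degC at 100 uM DNA, CD melting at 290 nm, 5-95 degC at 10 uM
#' DNA, spectra 210-330 nm, and 25 x 10 uL injections of 70 uM DNA into
#' 1.4 mL of 10 uM ligand.  Default noise levels are plausible instrument
#' magnitudes: 0.05 kcal mol-1 K-1 (DSC), 2 percent of signal range (CD
#' and spectra), 0.2 kcal per mol injectant (ITC).
#'
#' @param model true [system_model()]; defaults to [model_22gt()].
#' @param seed base RNG seed from which every dataset's noise seed is
#'   derived deterministically.
#' @param dsc,cd,spectra,itc named lists overriding individual menu
#'   entries (see the function body for the recognized keys).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(model = model_22gt(), seed = 1,
                          dsc = list(), cd = list(), spectra = list(),
                          itc = list()) {
  merge_menu <- function(defaults, user) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) {
      stop(sprintf("unknown scenario keys: %s (valid: %s)",
                   paste(bad, collapse = ", "),
                   paste(names(defaults), collapse = ", ")), call. = FALSE)
    }
    utils::modifyList(defaults, user)
  }
  dsc <- merge_menu(list(
    cK = c(0.001, 0.01, 0.1), tempC = seq(0.5, 95, by = 0.5),
    cDNA = 100e-6, intrinsic = c(1.4, 8e-3, -2e-5), sigma = 0.05), dsc)
  cd <- merge_menu(list(
    cK = c(0.001, 0.01, 0.1), tempC = seq(5, 95, by = 1), cDNA = 10e-6,
    wavelength = 290, fI = 0.3,
    baselineQ = c(2.1e5, -150), baselineU = c(3.5e4, -80),
    sigmaRel = 0.02), cd)
  spectra <- merge_menu(list(
    cK = 0.01, tempC = seq(5, 95, by = 2.5), wavelengths = seq(210, 330, by = 2),
    sigmaRel = 0.02), spectra)
  itc <- merge_menu(list(
    tempC = c(15, 25, 40), cK = 0.1, cellVolume = 1.4e-3, syringeDNA = 70e-6,
    cellLigand = 10e-6, injectionVolumes = rep(10e-6, 25),
    dilutionOffset = -0.4, sigma = 0.2), itc)
  structure(list(model = model, seed = as.integer(seed),
                 dsc = dsc, cd = cd, spectra = spectra, itc = itc),
            class = "scenario_spec")
}

#' One measured dataset with its conditions and nuisance slots
#'
#' @param kind `"DSC"`, `"CD"`, `"SPECTRA"` or `"ITC"`.
#' @param data the data table (a data.frame, or a matrix for spectra).
#' @param conditions named list of condition values (cK, cDNA, tempC,
#'   protocol, ... as the kind requires).
#' @param truth optional list with the generating parameters and the
#'   noiseless curve, carried by synthetic datasets.
#' @return An object of class `experiment_dataset`.
#' @export
experiment_dataset <- function(kind, data, conditions, truth = NULL) {
  kind <- match.arg(kind, c("DSC", "CD", "SPECTRA", "ITC"))
  structure(list(kind = kind, data = data, conditions = conditions,
                 truth = truth),
            class = "experiment_dataset")
}

# deterministic per-dataset noise draw; restores the caller's RNG state
with_noise <- function(seed, n, sigma) {
  state <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(state)) assign(".Random.seed", state, envir = globalenv()))
  set.seed(seed)
  stats::rnorm(n, sd = sigma)
}

#' Simulate DSC thermograms
#'
#' Partial molar heat capacity = quadratic intrinsic baseline + model
#' excess heat capacity + Gaussian noise, one thermogram per K+ level.
#' The noiseless curve and the generating parameters are stored in
#' `truth`.
#'
#' @param scenario a [scenario_spec()].
#' @return List of `experiment_dataset` objects of kind `"DSC"`.
#' @export
make_dsc <- function(scenario) {
  s <- scenario$dsc
  lapply(seq_along(s$cK), function(i) {
    cK <- s$cK[i]
    excess <- dsc_excess_cp(scenario$model, s$tempC, cK)
    intrinsic <- s$intrinsic[1] + s$intrinsic[2] * s$tempC +
      s$intrinsic[3] * s$tempC^2
    clean <- intrinsic + excess
    noise <- with_noise(scenario$seed + 101L * i, length(clean), s$sigma)
    experiment_dataset(
      "DSC",
      data.frame(temperature_C = s$tempC, cp_kcal_mol_K = clean + noise),
      conditions = list(cK = cK, cDNA = s$cDNA),
      truth = list(model = scenario$model, intrinsic = s$intrinsic,
                   noiseless = clean, sigma = s$sigma))
  })
}

# synthetic CD basis spectra: band shapes qualitatively emulating an
# antiparallel/hybrid quadruplex (Q: maxima 290/245, shoulder 270, minima
# 265/235), the two-quartet intermediate (I: maxima 290/245, minimum 265)
# and the unfolded strand (U: weak broad band), in molar-ellipticity units.
basis_spectra <- function(wavelengths) {
  band <- function(center, width, amp) amp * exp(-((wavelengths - center) / width)^2)
  Q <- band(290, 12, 2.1e5) + band(245, 8, 0.9e5) + band(270, 7, 0.6e5) -
    band(265, 8, 1.3e5) - band(235, 6, 0.8e5)
  I <- band(292, 11, 1.6e5) + band(247, 7, 1.0e5) -
    band(262, 7, 1.6e5) - band(233, 5, 0.4e5)
  U <- band(277, 14, 0.5e5) - band(250, 10, 0.45e5)
  cbind(Q = Q, I = I, U = U)
}

#' Simulate CD melting curves and temperature-series spectra
#'
#' Melting curves are the normalized three-state signal mapped through
#' linear instrument baselines plus noise (sigma = `sigmaRel` times the
#' baseline signal range), one per K+ level.  The spectra matrix is the
#' fraction-weighted combination of synthetic Q/I/U basis spectra plus
#' noise (sigma = `sigmaRel` times the maximum absolute signal).
#'
#' @param scenario a [scenario_spec()].
#' @return List with `curves` (list of kind-`"CD"` datasets) and `spectra`
#'   (one kind-`"SPECTRA"` dataset whose `data` is the wavelength x
#'   temperature matrix).
#' @export
make_cd <- function(scenario) {
  s <- scenario$cd
  curves <- lapply(seq_along(s$cK), function(i) {
    cK <- s$cK[i]
    clean <- cd_melting_curve(scenario$model, s$tempC, cK, s$fI,
                              s$baselineQ, s$baselineU)
    rng <- abs(s$baselineQ[1] - s$baselineU[1])
    noise <- with_noise(scenario$seed + 211L * i, length(clean),
                        s$sigmaRel * rng)
    experiment_dataset(
      "CD",
      data.frame(temperature_C = s$tempC, ellipticity = clean + noise),
      conditions = list(cK = cK, cDNA = s$cDNA, wavelength = s$wavelength),
      truth = list(model = scenario$model, fI = s$fI,
                   baselineQ = s$baselineQ, baselineU = s$baselineU,
                   noiseless = clean, sigmaRel = s$sigmaRel))
  })

  sp <- scenario$spectra
  basis <- basis_spectra(sp$wavelengths)
  fr <- fractions_free(scenario$model, celsius_to_kelvin(sp$tempC), sp$cK)
  clean <- basis %*% t(fr[, c("Q", "I", "U")])
  dimnames(clean) <- list(sp$wavelengths, sp$tempC)
  sigma <- sp$sigmaRel * max(abs(clean))
  noise <- matrix(with_noise(scenario$seed + 307L, length(clean), sigma),
                  nrow = nrow(clean))
  spectra <- experiment_dataset(
    "SPECTRA", clean + noise,
    conditions = list(cK = sp$cK, tempC = sp$tempC,
                      wavelengths = sp$wavelengths),
    truth = list(model = scenario$model, basis = basis, fractions = fr,
                 noiseless = clean, sigma = sigma))
  list(curves = curves, spectra = spectra)
}

#' Simulate ITC reverse-titration series
#'
#' Per-injection enthalpies of interaction from the mechanism's forward
#' model plus the dilution offset plus Gaussian noise, one series per
#' temperature.
#'
#' @param scenario a [scenario_spec()].
#' @return List of `experiment_dataset` objects of kind `"ITC"`.
#' @export
make_itc <- function(scenario) {
  s <- scenario$itc
  lapply(seq_along(s$tempC), function(i) {
    protocol <- itc_protocol(tempC = s$tempC[i], cK = s$cK,
                             cellVolume = s$cellVolume,
                             syringeDNA = s$syringeDNA,
                             cellLigand = s$cellLigand,
                             injectionVolumes = s$injectionVolumes)
    clean <- itc_heats(scenario$model, protocol, s$dilutionOffset)
    noise <- with_noise(scenario$seed + 401L * i, length(clean), s$sigma)
    experiment_dataset(
      "ITC",
      data.frame(injection_index = seq_along(clean),
                 volume_uL = s$injectionVolumes * 1e6,
                 heat_kcal_per_mol_DNA = clean + noise),
      conditions = list(protocol = protocol),
      truth = list(model = scenario$model, dilutionOffset = s$dilutionOffset,
                   noiseless = clean, sigma = s$sigma))
  })
}
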