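# Forward models mapping a speciation trajectory onto the three measured
# signals: normalized CD melting curves, DSC excess heat capacity, and ITC
# per-injection heats, plus the intermediate-spectrum estimator.

#' Normalized CD melting signal
#'
#' The normalized ellipticity `f = (theta - thetaQ) / (thetaU - thetaQ)`
#' expressed through species fractions as `f = alphaI * fI + alphaU`,
#' where `fI` is a temperature-independent normalization coefficient of
#' the intermediate (one adjustable scalar per melting curve).
#'
#' @param alphaI,alphaU fractions of the intermediate and unfolded species
#'   (vectors over temperature).  Ligand-complex fractions, if present,
#'   count with their conformational core (callers pass ligand-free
#'   trajectories here).
#' @param fI intermediate normalization coefficient (dimensionless).
#' @return Normalized signal `f` per temperature.
#' @export
cd_normalized <- function(alphaI, alphaU, fI) {
  alphaI * fI + alphaU
}

#' Map a normalized CD signal back to raw ellipticity
#'
#' Applies the linear pre- and post-transitional instrument baselines:
#' `theta(T) = thetaQ(T) + f * (thetaU(T) - thetaQ(T))` with
#' `thetaQ(T) = bQ[1] + bQ[2] * T` and likewise for `bU`.  Exact inverse
#' of [cd_normalize_raw()].
#'
#' @param f normalized signal per temperature.
#' @param tempC temperatures (degC).
#' @param baselineQ,baselineU numeric length-2 `(intercept, slope)` of the
#'   folded and unfolded baselines in raw ellipticity units per degC.
#' @return Raw ellipticity per temperature.
#' @export
cd_denormalize <- function(f, tempC, baselineQ, baselineU) {
  thQ <- baselineQ[1] + baselineQ[2] * tempC
  thU <- baselineU[1] + baselineU[2] * tempC
  if (any(thU == thQ)) {
    stop("degenerate baselines: thetaU(T) equals thetaQ(T) on the grid",
         call. = FALSE)
  }
  thQ + f * (thU - thQ)
}

#' @rdname cd_denormalize
#' @param theta raw ellipticity per temperature.
#' @export
cd_normalize_raw <- function(theta, tempC, baselineQ, baselineU) {
  thQ <- baselineQ[1] + baselineQ[2] * tempC
  thU <- baselineU[1] + baselineU[2] * tempC
  if (any(thU == thQ)) {
    stop("degenerate baselines: thetaU(T) equals thetaQ(T) on the grid",
         call. = FALSE)
  }
  (theta - thQ) / (thU - thQ)
}

#' Model CD melting curve at one K+ concentration
#'
#' Ligand-free three-state trajectory mapped through the normalized signal
#' and the instrument baselines.
#'
#' @param model a [system_model()].
#' @param tempC temperatures (degC).
#' @param cK K+ concentration (mol/L).
#' @param fI intermediate normalization coefficient.
#' @param baselineQ,baselineU linear baseline coefficients; if omitted the
#'   normalized signal is returned.
#' @return Ellipticity (raw if baselines given, else normalized).
#' @export
cd_melting_curve <- function(model, tempC, cK, fI,
                             baselineQ = NULL, baselineU = NULL) {
  fr <- fractions_free(model, celsius_to_kelvin(tempC), cK)
  f <- cd_normalized(fr[, "I"], fr[, "U"], fI)
  if (is.null(baselineQ)) return(f)
  cd_denormalize(f, tempC, baselineQ, baselineU)
}

#' Mean excess enthalpy of the mixture
#'
#' `<dH>(T) = sum_s alpha_s(T) H_s(T)` with species enthalpies relative to
#' the unfolded strand, over a ligand-free trajectory.
#'
#' @param model a [system_model()].
#' @param T absolute temperatures (K), vector.
#' @param cK K+ concentration (mol/L).
#' @return Mean enthalpy per mol strand (kcal/mol) per temperature.
#' @export
mean_excess_enthalpy <- function(model, T, cK) {
  fr <- fractions_free(model, T, cK)
  ref <- model$ref
  hI <- step_enthalpy(model$transitions[[1]], T, ref)
  hQ <- hI + step_enthalpy(model$transitions[[2]], T, ref)
  fr[, "I"] * hI + fr[, "Q"] * hQ
}

#' Model DSC excess heat capacity
#'
#' The excess heat capacity of the folding mechanism,
#' `dCP(T) = d<dH>/dT`, computed by centered differences of the mean
#' excess enthalpy on a dense internal grid (default step 0.1 K) and
#' interpolated back to the requested grid.  The integral of the returned
#' curve over the full transition equals `<dH>(T_high) - <dH>(T_low)`.
#'
#' @param model a [system_model()].
#' @param tempC output temperatures (degC).
#' @param cK K+ concentration (mol/L).
#' @param step internal differentiation grid step (K); a warning is issued
#'   above 1 K.
#' @return Excess heat capacity (kcal mol-1 K-1) on `tempC`.
#' @export
dsc_excess_cp <- function(model, tempC, cK, step = 0.1) {
  if (step > 1) warning("excess-Cp grid step > 1 K; curve may be inaccurate")
  T <- celsius_to_kelvin(tempC)
  grid <- seq(min(T) - step, max(T) + step, by = step)
  h <- mean_excess_enthalpy(model, grid, cK)
  k <- seq(2, length(grid) - 1)
  dh <- (h[k + 1] - h[k - 1]) / (2 * step)
  stats::approx(grid[k], dh, xout = T, rule = 2)$y
}

#' Fit the intrinsic DSC baseline
#'
#' Least-squares second-order polynomial through the union of a
#' low-temperature (folded) and a high-temperature (unfolded) window of a
#' measured thermogram; subtracting it yields the excess heat capacity.
#'
#' @param tempC temperatures (degC).
#' @param cp partial molar heat capacity (kcal mol-1 K-1).
#' @param lowWindow,highWindow length-2 degC ranges; each must contain at
#'   least 5 grid points.
#' @return List with `coef` (quadratic coefficients c0 + c1 T + c2 T^2),
#'   `baseline` and `excess` on the input grid.
#' @export
dsc_intrinsic_baseline <- function(tempC, cp,
                                   lowWindow = c(0.5, 15),
                                   highWindow = c(85, 95)) {
  inwin <- function(w) tempC >= w[1] & tempC <= w[2]
  lo <- inwin(lowWindow); hi <- inwin(highWindow)
  if (sum(lo) < 5) stop("low-temperature window contains fewer than 5 points",
                        call. = FALSE)
  if (sum(hi) < 5) stop("high-temperature window contains fewer than 5 points",
                        call. = FALSE)
  sel <- lo | hi
  fit <- stats::lm(cp[sel] ~ tempC[sel] + I(tempC[sel]^2))
  cf <- unname(stats::coef(fit))
  baseline <- cf[1] + cf[2] * tempC + cf[3] * tempC^2
  list(coef = cf, baseline = baseline, excess = cp - baseline)
}

#' ITC titration protocol
#'
#' Reverse-titration protocol: DNA titrated from the syringe into a ligand
#' solution in the cell.  Defaults emulate 25 x 10 uL injections of 70 uM
#' DNA into 1.4 mL of 10 uM ligand.
#'
#' @param tempC cell temperature (degC).
#' @param cK K+ concentration (mol/L).
#' @param cellVolume active cell volume (L).
#' @param syringeDNA DNA strand concentration in the syringe (mol/L).
#' @param cellLigand initial ligand concentration in the cell (mol/L).
#' @param injectionVolumes per-injection volumes (L).
#' @return An object of class `itc_protocol`.
#' @export
itc_protocol <- function(tempC = 25, cK = 0.1,
                         cellVolume = 1.4e-3,
                         syringeDNA = 70e-6,
                         cellLigand = 10e-6,
                         injectionVolumes = rep(10e-6, 25)) {
  stopifnot(cellVolume > 0, all(injectionVolumes > 0),
            syringeDNA >= 0, cellLigand >= 0)
  structure(list(tempC = tempC, cK = cK, cellVolume = cellVolume,
                 syringeDNA = syringeDNA, cellLigand = cellLigand,
                 injectionVolumes = injectionVolumes),
            class = "itc_protocol")
}

#' Model ITC per-injection heats
#'
#' For each injection the cell totals are updated by the
#' instantaneous-displacement convention (the injected volume displaces an
#' equal volume of pre-injection cell composition), the speciation is
#' solved before and after, and the heat is the enthalpy content change of
#' the cell corrected for the displaced and injected material:
#'
#'   Q_k = V0 sum_s H_s [s]_after - (V0 - v) sum_s H_s [s]_before
#'         - v sum_s H_s [s]_syringe
#'
#' expressed per mole of DNA added in the injection, plus a constant
#' per-injection dilution offset.  Species enthalpies are relative to U
#' and free ligand; the syringe content is taken pre-equilibrated at the
#' cell temperature.
#'
#' @param model a [system_model()].
#' @param protocol an [itc_protocol()].
#' @param dilutionOffset constant heat per injection (kcal per mol DNA
#'   injected).
#' @return Numeric vector of per-injection enthalpies of interaction
#'   (kcal per mol DNA injected).
#' @export
itc_heats <- function(model, protocol, dilutionOffset = 0) {
  T <- celsius_to_kelvin(protocol$tempC)
  V0 <- protocol$cellVolume
  H <- species_enthalpies(model, T)
  vols <- protocol$injectionVolumes
  nInj <- length(vols)

  # cell totals after each injection (displacement bookkeeping is purely
  # compositional, so all post-injection states are known up front and the
  # speciation solves run in lock-step)
  cDNA <- numeric(nInj); cL <- numeric(nInj)
  d <- 0; l <- protocol$cellLigand
  for (k in seq_len(nInj)) {
    keep <- 1 - vols[k] / V0
    d <- d * keep + protocol$syringeDNA * (vols[k] / V0)
    l <- l * keep
    cDNA[k] <- d; cL[k] <- l
  }

  states_cDNA <- c(protocol$syringeDNA, 0, cDNA)
  states_cL <- c(0, protocol$cellLigand, cL)
  sg <- speciation_grid(model, rep(T, nInj + 2), rep(protocol$cK, nInj + 2),
                        states_cDNA, states_cL)
  # volumetric enthalpy content, kcal per L of solution
  h <- states_cDNA * as.numeric(sg$fractions %*% H)
  hSyr <- h[1]
  hCell <- h[-1]  # initial cell then after injection 1..nInj
  q <- V0 * hCell[-1] - (V0 - vols) * hCell[-(nInj + 1)] - vols * hSyr
  q / (vols * protocol$syringeDNA) + dilutionOffset
}

#' Estimate the spectrum of the folding intermediate
#'
#' Describes a temperature-series spectra matrix as a linear combination
#' of the folded (Q), intermediate (I, unknown) and unfolded (U) spectra
#' weighted by model-predicted fractions, and solves per wavelength for
#' the intermediate spectrum by least squares:
#' `theta(lambda, T) - alphaQ Q(lambda) - alphaU U(lambda) = alphaI I(lambda)`.
#'
#' @param spectra matrix, wavelengths x temperatures.
#' @param fractions matrix, temperatures x 3 with columns `U`, `I`, `Q`
#'   (model-predicted trajectory on the same temperatures).
#' @param spectrumQ,spectrumU reference spectra of the folded and unfolded
#'   forms on the same wavelength grid.
#' @return List with `spectrumI` (per wavelength) and `residualNorm`
#'   (Frobenius norm of the unexplained part).
#' @export
estimate_intermediate_spectrum <- function(spectra, fractions,
                                           spectrumQ, spectrumU) {
  stopifnot(ncol(spectra) == nrow(fractions),
            length(spectrumQ) == nrow(spectra),
            length(spectrumU) == nrow(spectra))
  aI <- fractions[, "I"]
  ss <- sum(aI^2)
  if (ss < 1e-12) {
    stop("intermediate fraction is (near) zero at every temperature; its spectrum is unidentifiable",
         call. = FALSE)
  }
  resid <- spectra - outer(spectrumQ, fractions[, "Q"]) -
    outer(spectrumU, fractions[, "U"])
  specI <- as.numeric(resid %*% aI) / ss
  leftover <- resid - outer(specI, aI)
  list(spectrumI = specI, residualNorm = sqrt(sum(leftover^2)))
}
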