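# Linked-equilibrium model of quadruplex folding and ligand binding.
#
# Species (per DNA strand): U (unfolded), I (two-quartet intermediate, one
# specifically bound K+), Q (folded quadruplex, two K+), and the ligand
# complexes QL, IL (ligand on the bottom site, "site 2"), LI (ligand on the
# upper site, "site 1", accessible only on I) and LIL (both sites occupied
# on I).  Folding steps exchange K+ ions; binding steps do not.  All
# standard-state parameters are stored at one reference condition and
# propagated with Gibbs-Helmholtz and ion-linkage terms.

SPECIES <- c("U", "I", "Q", "QL", "IL", "LI", "LIL")

# ligand stoichiometry per species, in SPECIES order
LIGANDS_PER_SPECIES <- c(U = 0, I = 0, Q = 0, QL = 1, IL = 1, LI = 1, LIL = 2)

#' Reference conditions for standard-state parameters
#'
#' All transition and binding parameters are stored at one reference state
#' and propagated to other conditions; the default reference is 25 degC and
#' 100 mM K+.
#'
#' @param T0 reference absolute temperature (K).
#' @param cref reference K+ concentration (mol/L).
#' @return An object of class `ref_conditions` with fields `T0`, `cref` and
#'   the gas constant `R` (kcal mol-1 K-1, fixed).
#' @export
ref_conditions <- function(T0 = 298.15, cref = 0.1) {
  if (!is.finite(T0) || T0 <= 0) stop_domain("T0", T0)
  if (!is.finite(cref) || cref <= 0) stop_domain("cref", cref)
  structure(list(T0 = T0, cref = cref, R = gas_constant()),
            class = "ref_conditions")
}

#' Standard thermodynamics of one folding transition
#'
#' One step of the folding pathway U -> I -> Q, parameterized at the
#' reference condition by the Gibbs energy, enthalpy, heat-capacity change
#' and the signed number of exchanged K+ ions.  The entropic term is always
#' derived as `dH0 - dG0` and never stored independently.
#'
#' @param name transition label, `"U->I"` or `"I->Q"`.
#' @param dG0 standard Gibbs energy at reference (kcal/mol).
#' @param dH0 standard enthalpy at reference (kcal/mol).
#' @param dCp heat-capacity change (kcal mol-1 K-1).
#' @param n number of K+ ions exchanged along the step (signed; negative
#'   means ions are taken up on folding written in the U -> Q direction).
#' @return An object of class `transition_thermo`.
#' @export
transition_thermo <- function(name, dG0, dH0, dCp, n) {
  name <- match.arg(name, c("U->I", "I->Q"))
  vals <- c(dG0 = dG0, dH0 = dH0, dCp = dCp, n = n)
  if (any(!is.finite(vals))) stop_domain(names(vals)[!is.finite(vals)][1], vals)
  structure(list(name = name, dG0 = dG0, dH0 = dH0, dCp = dCp, n = n),
            class = "transition_thermo")
}

#' Per-site ligand-binding thermodynamics
#'
#' Site 1 is the upper end exposed only on the intermediate after loss of
#' one specific K+ (`I + L -> LI`); site 2 is the bottom end shared by the
#' Q and I forms (`Q + L -> QL`, `I + L -> IL`, `LI + L -> LIL`), with one
#' common parameter set.  Binding steps exchange no K+, so site parameters
#' carry no salt linkage.
#'
#' @param site site label, 1 or 2.
#' @param dG0 binding Gibbs energy at reference (kcal/mol).
#' @param dH0 binding enthalpy at reference (kcal/mol).
#' @param dCp binding heat-capacity change (kcal mol-1 K-1).
#' @return An object of class `site_thermo`.
#' @export
site_thermo <- function(site, dG0, dH0, dCp) {
  if (!site %in% c(1, 2)) stop_domain("site", site)
  vals <- c(dG0 = dG0, dH0 = dH0, dCp = dCp)
  if (any(!is.finite(vals))) stop_domain(names(vals)[!is.finite(vals)][1], vals)
  structure(list(site = as.integer(site), dG0 = dG0, dH0 = dH0, dCp = dCp),
            class = "site_thermo")
}

#' Assemble the seven-species system model
#'
#' @param transitions list of the two [transition_thermo()] records
#'   (`U->I`, `I->Q`, in that order or named).
#' @param sites list of the two [site_thermo()] records (site 1, site 2).
#' @param ref a [ref_conditions()] object.
#' @return An object of class `system_model` with fixed ordered species
#'   list `U, I, Q, QL, IL, LI, LIL`.  No ligand binding to U and no LQ
#'   species exist in the mechanism.
#' @export
system_model <- function(transitions, sites, ref = ref_conditions()) {
  stopifnot(length(transitions) == 2L, length(sites) == 2L)
  nm <- vapply(transitions, function(t) t$name, character(1))
  if (!setequal(nm, c("U->I", "I->Q"))) {
    stop("transitions must be one 'U->I' and one 'I->Q' record", call. = FALSE)
  }
  transitions <- transitions[order(match(nm, c("U->I", "I->Q")))]
  sn <- vapply(sites, function(s) s$site, integer(1))
  if (!setequal(sn, 1:2)) stop("sites must be labelled 1 and 2", call. = FALSE)
  sites <- sites[order(sn)]
  structure(list(transitions = transitions, sites = sites, ref = ref,
                 species = SPECIES),
            class = "system_model")
}

#' Published 22GT/360A parameter set
#'
#' The standard thermodynamic parameters of 22GT
#' (5'-GGGTTAGGGTTAGGGTTAGGGT-3') folding and of 360A binding at the 25
#' degC, 100 mM K+ reference: U->I (-4.7, -34, -0.22, n = -1.3), I->Q
#' (-1.0, -22, -0.1, n = -0.4), site 1 (-9.6, -18, -0.02) and site 2
#' (-8.7, -20, -0.16).  This set is the default truth of the synthetic-data
#' generator.
#'
#' @return A [system_model()].
#' @export
model_22gt <- function() {
  system_model(
    transitions = list(
      transition_thermo("U->I", dG0 = -4.7, dH0 = -34, dCp = -0.22, n = -1.3),
      transition_thermo("I->Q", dG0 = -1.0, dH0 = -22, dCp = -0.10, n = -0.4)),
    sites = list(
      site_thermo(1, dG0 = -9.6, dH0 = -18, dCp = -0.02),
      site_thermo(2, dG0 = -8.7, dH0 = -20, dCp = -0.16)),
    ref = ref_conditions())
}

#' Experimental conditions
#'
#' @param T absolute temperature (K), within 273-380 K.
#' @param cK K+ concentration (mol/L), > 0.
#' @param cDNA total strand concentration (mol/L), >= 0.
#' @param cL total ligand concentration (mol/L), >= 0.
#' @return An object of class `conditions`; the ligand/DNA molar ratio `r`
#'   is derived on access via [molar_ratio()], never stored.
#' @export
conditions <- function(T, cK, cDNA = 0, cL = 0) {
  if (!is.finite(T) || T < 273 || T > 380) stop_domain("T", T)
  if (!is.finite(cK) || cK <= 0) stop_domain("cK", cK)
  if (!is.finite(cDNA) || cDNA < 0) stop_domain("cDNA", cDNA)
  if (!is.finite(cL) || cL < 0) stop_domain("cL", cL)
  structure(list(T = T, cK = cK, cDNA = cDNA, cL = cL), class = "conditions")
}

#' @rdname conditions
#' @param cond a `conditions` object.
#' @export
molar_ratio <- function(cond) {
  if (cond$cDNA <= 0) return(NA_real_)
  cond$cL / cond$cDNA
}

#' Standard Gibbs energy of a step at arbitrary temperature and salt
#'
#' Propagates a stored reference-state parameter set to temperature `T`
#' via the Gibbs-Helmholtz relation with constant heat-capacity change,
#'
#'   dG(T) = dH0 - T (dH0 - dG0)/T0 + dCp ((T - T0) - T log(T/T0)),
#'
#' and, for folding transitions only, adds the K+ linkage term
#' `n R T log(cK / cref)`.  Ligand-binding sites exchange no ions and carry
#' no salt term.  Activities are taken equal to molar concentrations.
#'
#' @param x a [transition_thermo()] or [site_thermo()] record.
#' @param T absolute temperature (K); vectorized.
#' @param cK K+ concentration (mol/L); vectorized with `T`.
#' @param ref a [ref_conditions()] object.
#' @return Standard Gibbs energy in kcal/mol; at `(T0, cref)` returns `dG0`
#'   exactly.
#' @export
gibbs_energy <- function(x, T, cK = NULL, ref = ref_conditions()) {
  if (any(!is.finite(T)) || any(T <= 0)) stop_domain("T", T)
  dG <- gibbs_helmholtz(x$dG0, x$dH0, x$dCp, T, ref$T0)
  if (inherits(x, "transition_thermo")) {
    if (is.null(cK)) stop("cK is required for a folding transition", call. = FALSE)
    if (any(!is.finite(cK)) || any(cK <= 0)) stop_domain("cK", cK)
    dG <- dG + x$n * ref$R * T * log(cK / ref$cref)
  }
  dG
}

gibbs_helmholtz <- function(dG0, dH0, dCp, T, T0) {
  dH0 - T * (dH0 - dG0) / T0 + dCp * ((T - T0) - T * log(T / T0))
}

#' Standard enthalpy of a step at arbitrary temperature
#'
#' Kirchhoff propagation `dH(T) = dH0 + dCp (T - T0)`.
#'
#' @inheritParams gibbs_energy
#' @return Enthalpy in kcal/mol.
#' @export
step_enthalpy <- function(x, T, ref = ref_conditions()) {
  if (any(!is.finite(T)) || any(T <= 0)) stop_domain("T", T)
  x$dH0 + x$dCp * (T - ref$T0)
}

#' Equilibrium constant from a standard Gibbs energy
#'
#' @param dG standard Gibbs energy (kcal/mol).
#' @param T absolute temperature (K).
#' @return `exp(-dG / (R T))`, dimensionless (or per molar for a binding
#'   step); strictly positive and monotone decreasing in `dG`.
#' @export
equilibrium_constant <- function(dG, T) {
  if (any(!is.finite(T)) || any(T <= 0)) stop_domain("T", T)
  exp(-dG / (gas_constant() * T))
}

#' Species enthalpies relative to the unfolded strand
#'
#' Path sums of step enthalpies from U at temperature `T`; the unfolded
#' strand is the zero level, matching the baseline convention of the DSC
#' analysis.  Path independence (`IL -> LIL` vs `LI -> LIL`) holds by
#' construction since site 2 is shared.
#'
#' @param model a [system_model()].
#' @param T absolute temperature (K), scalar.
#' @return Named numeric vector over the seven species (kcal/mol).
#' @export
species_enthalpies <- function(model, T) {
  ref <- model$ref
  hUI <- step_enthalpy(model$transitions[[1]], T, ref)
  hIQ <- step_enthalpy(model$transitions[[2]], T, ref)
  h1 <- step_enthalpy(model$sites[[1]], T, ref)
  h2 <- step_enthalpy(model$sites[[2]], T, ref)
  c(U = 0, I = hUI, Q = hUI + hIQ,
    QL = hUI + hIQ + h2, IL = hUI + h2, LI = hUI + h1,
    LIL = hUI + h1 + h2)
}

# Species standard Gibbs energies relative to U (folding part, vectorized
# over T/cK) plus the two binding energies; everything downstream of here
# works with these five numbers.
species_energies <- function(model, T, cK) {
  ref <- model$ref
  gI <- gibbs_energy(model$transitions[[1]], T, cK, ref)
  gQ <- gI + gibbs_energy(model$transitions[[2]], T, cK, ref)
  g1 <- gibbs_energy(model$sites[[1]], T, ref = ref)
  g2 <- gibbs_energy(model$sites[[2]], T, ref = ref)
  list(gI = gI, gQ = gQ, g1 = g1, g2 = g2)
}

# Per-strand species weights at free-ligand concentration L (may be a
# vector), as a length(L) x 7 matrix of relative Boltzmann weights,
# normalized to sum 1 per row.  Log-space with max subtraction so that
# strongly folded conditions cannot overflow.
species_fractions_given_L <- function(en, RT, L) {
  lw <- cbind(U = 0,
              I = -en$gI / RT,
              Q = -en$gQ / RT)
  lL <- ifelse(L > 0, log(L), -Inf)
  lK1 <- -en$g1 / RT
  lK2 <- -en$g2 / RT
  lw <- cbind(lw,
              QL  = lw[, "Q"] + lK2 + lL,
              IL  = lw[, "I"] + lK2 + lL,
              LI  = lw[, "I"] + lK1 + lL,
              LIL = lw[, "I"] + lK1 + lK2 + 2 * lL)
  m <- apply(lw, 1, max)
  w <- exp(lw - m)
  w / rowSums(w)
}

#' Solve the mass-action speciation problem
#'
#' Finds the equilibrium distribution of the seven species and the free
#' ligand concentration at one condition.  DNA-species proportions at a
#' given free-ligand concentration follow the mass-action relations of the
#' mechanism; the free ligand is the root of the (monotone) ligand
#' conservation function on `[0, cL]`, located by bisection and polished
#' by Newton steps to relative tolerance 1e-10.
#'
#' @param model a [system_model()].
#' @param cond a [conditions()] object.
#' @return An object of class `speciation`: `fractions` (named over the
#'   seven species, summing to 1), `freeLigand` (mol/L), and the `cond`
#'   used.  With `cL = 0` all complex fractions are exactly zero.
#' @export
solve_speciation <- function(model, cond) {
  stopifnot(inherits(cond, "conditions"))
  RT <- gas_constant() * cond$T
  en <- species_energies(model, cond$T, cond$cK)

  bound <- function(L) {
    fr <- species_fractions_given_L(en, RT, L)
    cond$cDNA * as.numeric(fr %*% LIGANDS_PER_SPECIES)
  }

  if (cond$cL == 0 || cond$cDNA == 0) {
    L <- cond$cL
  } else {
    g <- function(L) L + bound(L) - cond$cL
    lo <- 0; hi <- cond$cL
    glo <- g(lo); ghi <- g(hi)
    if (glo > 0 || ghi < 0) {
      stop(sprintf(
        "speciation: failed to bracket free ligand at T=%.2f K, cK=%g M (residuals %.3g, %.3g)",
        cond$T, cond$cK, glo, ghi), call. = FALSE)
    }
    for (i in seq_len(100)) {
      mid <- 0.5 * (lo + hi)
      if (g(mid) > 0) hi <- mid else lo <- mid
      if ((hi - lo) <= 1e-12 * max(hi, 1e-300)) break
    }
    L <- 0.5 * (lo + hi)
    # Newton polish on the conservation residual
    for (i in seq_len(4)) {
      h <- max(L * 1e-7, 1e-18)
      gl <- g(L)
      dg <- (g(L + h) - g(L - h)) / (2 * h)
      if (!is.finite(dg) || dg <= 0) break
      Lnew <- L - gl / dg
      if (Lnew <= 0 || Lnew >= cond$cL) break
      L <- Lnew
      if (abs(gl) <= 1e-10 * cond$cL) break
    }
    resid <- abs(L + bound(L) - cond$cL)
    if (resid > 1e-8 * cond$cL) {
      stop(sprintf(
        "speciation: free-ligand solve did not converge at T=%.2f K (residual %.3g)",
        cond$T, resid), call. = FALSE)
    }
  }

  fr <- drop(species_fractions_given_L(en, RT, L))
  structure(list(fractions = fr, freeLigand = L, cond = cond),
            class = "speciation")
}

#' Ligand-free species fractions over a temperature grid
#'
#' Closed-form three-state Boltzmann fractions of U, I and Q (no solver
#' needed when `cL = 0`), vectorized over temperature.
#'
#' @param model a [system_model()].
#' @param T absolute temperatures (K), vector.
#' @param cK K+ concentration (mol/L), scalar or vector matching `T`.
#' @return Matrix `length(T) x 3` with columns `U`, `I`, `Q`.
#' @export
fractions_free <- function(model, T, cK) {
  RT <- gas_constant() * T
  en <- species_energies(model, T, cK)
  lw <- cbind(U = rep(0, length(T)), I = -en$gI / RT, Q = -en$gQ / RT)
  m <- apply(lw, 1, max)
  w <- exp(lw - m)
  w / rowSums(w)
}

# Vectorized speciation over many conditions (one root solve per cell run
# in lock-step by vectorized bisection); used by the phase-diagram grids.
# Tvec, cKvec, cDNAvec, cLvec: equal-length vectors.  Returns an n x 7
# fraction matrix plus the free-ligand vector.
speciation_grid <- function(model, Tvec, cKvec, cDNAvec, cLvec) {
  n <- length(Tvec)
  RT <- gas_constant() * Tvec
  en <- species_energies(model, Tvec, cKvec)
  nu <- LIGANDS_PER_SPECIES

  boundv <- function(L) {
    fr <- species_fractions_given_L(en, RT, L)
    cDNAvec * as.numeric(fr %*% nu)
  }

  L <- cLvec
  active <- cLvec > 0 & cDNAvec > 0
  if (any(active)) {
    lo <- rep(0, n); hi <- cLvec
    for (i in seq_len(60)) {
      mid <- 0.5 * (lo + hi)
      over <- mid + boundv(mid) - cLvec > 0
      hi <- ifelse(active & over, mid, hi)
      lo <- ifelse(active & !over, mid, lo)
    }
    L <- ifelse(active, 0.5 * (lo + hi), cLvec)
  }
  fr <- species_fractions_given_L(en, RT, L)
  list(fractions = fr, freeLigand = L)
}
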