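# Binding free-energy decomposition and stability pseudophase diagrams.

#' Decompose a binding free energy into driving forces
#'
#' Splits the standard binding Gibbs energy at 25 degC into a hydration
#' term `Ghyd = 80 K * dCp` (dehydration of hydrophobic surface, with the
#' 80 (+/- 10) K factor fixed at 80 for point estimates), a specific
#' interaction term approximated by the binding enthalpy `Gint = dH0`,
#' and a remainder `Gother = dG0 - Ghyd - Gint` (rotational/translational
#' and conformational entropy costs).  The closure
#' `Gtotal = Ghyd + Gint + Gother` is exact by construction.
#'
#' @param site a [site_thermo()] record at the 25 degC reference.
#' @return An object of class `energy_decomposition` with fields `site`,
#'   `Gtotal`, `Ghyd`, `Gint`, `Gother` (kcal/mol).
#' @export
decompose_binding <- function(site) {
  stopifnot(inherits(site, "site_thermo"))
  Ghyd <- 80 * site$dCp
  Gint <- site$dH0
  Gother <- site$dG0 - Ghyd - Gint
  structure(list(site = site$site, Gtotal = site$dG0,
                 Ghyd = Ghyd, Gint = Gint, Gother = Gother),
            class = "energy_decomposition")
}

# fractions at one phase-space point (x, tC); x is log10[K+] for kind
# "logK" (at fixed molar ratio r) or the molar ratio r for kind "r" (at
# fixed [K+])
phase_point_fractions <- function(model, kind, x, tC, cDNA, cK, r) {
  if (kind == "logK") {
    cond <- conditions(celsius_to_kelvin(tC), 10^x, cDNA, r * cDNA)
  } else {
    cond <- conditions(celsius_to_kelvin(tC), cK, cDNA, x * cDNA)
  }
  solve_speciation(model, cond)$fractions
}

#' Dominant-species map over a condition grid
#'
#' Labels every cell of a 2-D condition grid (temperature against
#' log10[K+] at fixed ligand/DNA ratio, or against the ligand/DNA molar
#' ratio r at fixed [K+]) with the most populated species, the
#' pseudophase.  Ties within 1e-12 are resolved by species-list order.
#'
#' @param model a [system_model()].
#' @param kind `"logK"` (x = log10 of K+ molarity) or `"r"` (x = molar
#'   ratio cL/cDNA).
#' @param xGrid x-axis grid (default log10[K+] in \[-4, -1\] or r in
#'   \[0, 3\], 200 points).
#' @param tempC temperature grid (degC, default 0-95, 200 points).
#' @param cDNA total strand concentration (mol/L, default 10 uM).
#' @param cK fixed K+ concentration for `kind = "r"` (mol/L).
#' @param r fixed molar ratio for `kind = "logK"`.
#' @return An object of class `phase_diagram`: the axes, a
#'   `length(xGrid) x length(tempC)` character matrix of labels, and the
#'   call parameters.
#' @export
dominant_species_map <- function(model, kind = c("logK", "r"),
                                 xGrid = NULL,
                                 tempC = seq(0, 95, length.out = 200),
                                 cDNA = 10e-6, cK = 0.1, r = 0) {
  kind <- match.arg(kind)
  if (is.null(xGrid)) {
    xGrid <- if (kind == "logK") seq(-4, -1, length.out = 200)
             else seq(0, 3, length.out = 200)
  }
  if (length(xGrid) < 2 || length(tempC) < 2) {
    stop("grid must be at least 2 x 2", call. = FALSE)
  }
  cells <- expand.grid(x = xGrid, tC = tempC)
  T <- celsius_to_kelvin(cells$tC)
  if (kind == "logK") {
    cKv <- 10^cells$x
    cLv <- rep(r * cDNA, nrow(cells))
  } else {
    cKv <- rep(cK, nrow(cells))
    cLv <- cells$x * cDNA
  }
  sg <- speciation_grid(model, T, cKv, rep(cDNA, nrow(cells)), cLv)
  fr <- sg$fractions
  lab <- apply(fr, 1, function(f) SPECIES[which(f >= max(f) - 1e-12)][1])
  labels <- matrix(lab, nrow = length(xGrid), ncol = length(tempC),
                   dimnames = list(format(xGrid), format(tempC)))
  structure(list(kind = kind, xGrid = xGrid, tempC = tempC,
                 labels = labels, cDNA = cDNA, cK = cK, r = r,
                 model = model),
            class = "phase_diagram")
}

# bisect between two phase-space points until the two named fractions tie
tie_bisect <- function(model, diagram, p1, p2, spA, spB, tol = 1e-6,
                       maxit = 200) {
  fdiff <- function(p) {
    fr <- phase_point_fractions(model, diagram$kind, p[1], p[2],
                                diagram$cDNA, diagram$cK, diagram$r)
    fr[spA] - fr[spB]
  }
  d1 <- fdiff(p1); d2 <- fdiff(p2)
  if (sign(d1) == sign(d2)) return(NULL)
  for (i in seq_len(maxit)) {
    mid <- 0.5 * (p1 + p2)
    dm <- fdiff(mid)
    if (abs(dm) < tol) return(mid)
    if (sign(dm) == sign(d1)) { p1 <- mid; d1 <- dm } else { p2 <- mid; d2 <- dm }
  }
  NULL
}

#' Refine pseudophase boundaries and triple points
#'
#' For every pair of adjacent grid cells whose labels differ, bisects
#' along the connecting segment until the two species' fractions are
#' equal within `tol` (default 1e-6); non-convergent segments are dropped
#' with a warning.  Triple points are located wherever 2 x 2 cell blocks
#' carry three or more labels, by two-dimensional root refinement of the
#' two pairwise tie conditions.
#'
#' @param diagram a [dominant_species_map()] result.
#' @param model the [system_model()] used to build it.
#' @param tol equal-fraction tolerance for boundary points.
#' @return List with `boundaries` (data frame: `x`, `tempC`, `speciesA`,
#'   `speciesB`) and `triplePoints` (data frame: `x`, `tempC`, the three
#'   species, and the largest pairwise fraction mismatch `maxGap`).
#' @export
trace_boundaries <- function(diagram, model = diagram$model, tol = 1e-6) {
  lab <- diagram$labels
  nx <- nrow(lab); ny <- ncol(lab)
  xg <- diagram$xGrid; tg <- diagram$tempC
  pts <- list(); dropped <- 0L

  scan_pair <- function(i1, j1, i2, j2) {
    a <- lab[i1, j1]; b <- lab[i2, j2]
    if (a == b) return(NULL)
    p <- tie_bisect(model, diagram, c(xg[i1], tg[j1]), c(xg[i2], tg[j2]),
                    a, b, tol)
    if (is.null(p)) { dropped <<- dropped + 1L; return(NULL) }
    sp <- sort(c(a, b))
    data.frame(x = p[1], tempC = p[2], speciesA = sp[1], speciesB = sp[2])
  }
  for (i in seq_len(nx - 1)) {
    for (j in seq_len(ny)) {
      pts[[length(pts) + 1L]] <- scan_pair(i, j, i + 1, j)
    }
  }
  for (i in seq_len(nx)) {
    for (j in seq_len(ny - 1)) {
      pts[[length(pts) + 1L]] <- scan_pair(i, j, i, j + 1)
    }
  }
  if (dropped > 0) {
    warning(sprintf("%d boundary segments did not converge and were dropped",
                    dropped))
  }
  boundaries <- if (length(pts)) do.call(rbind, pts) else
    data.frame(x = numeric(), tempC = numeric(),
               speciesA = character(), speciesB = character())
  if (nrow(boundaries)) {
    ord <- order(boundaries$speciesA, boundaries$speciesB, boundaries$tempC,
                 boundaries$x)
    boundaries <- boundaries[ord, , drop = FALSE]
    rownames(boundaries) <- NULL
  }

  # triple points: 2x2 blocks carrying >= 3 labels
  tps <- list()
  seen <- character()
  for (i in seq_len(nx - 1)) {
    for (j in seq_len(ny - 1)) {
      blk <- c(lab[i, j], lab[i + 1, j], lab[i, j + 1], lab[i + 1, j + 1])
      us <- unique(blk)
      if (length(us) < 3) next
      trio <- sort(us[1:3])
      key <- paste(trio, collapse = "-")
      if (key %in% seen) next
      p0 <- c(mean(xg[i:(i + 1)]), mean(tg[j:(j + 1)]))
      obj <- function(p) {
        fr <- tryCatch(
          phase_point_fractions(model, diagram$kind, p[1], p[2],
                                diagram$cDNA, diagram$cK, diagram$r),
          error = function(e) NULL)
        if (is.null(fr)) return(1e6)
        (fr[trio[1]] - fr[trio[2]])^2 + (fr[trio[1]] - fr[trio[3]])^2
      }
      opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                          control = list(reltol = 1e-16, maxit = 2000))
      # keep only junctions refined within the diagram window
      if (opt$par[1] < min(xg) || opt$par[1] > max(xg) ||
          opt$par[2] < min(tg) || opt$par[2] > max(tg)) next
      fr <- phase_point_fractions(model, diagram$kind, opt$par[1], opt$par[2],
                                  diagram$cDNA, diagram$cK, diagram$r)
      gap <- max(abs(c(fr[trio[1]] - fr[trio[2]], fr[trio[1]] - fr[trio[3]],
                       fr[trio[2]] - fr[trio[3]])))
      seen <- c(seen, key)
      tps[[length(tps) + 1L]] <- data.frame(
        x = opt$par[1], tempC = opt$par[2],
        species1 = trio[1], species2 = trio[2], species3 = trio[3],
        maxGap = gap)
    }
  }
  triple <- if (length(tps)) do.call(rbind, tps) else
    data.frame(x = numeric(), tempC = numeric(), species1 = character(),
               species2 = character(), species3 = character(),
               maxGap = numeric())
  rownames(triple) <- NULL
  list(boundaries = boundaries, triplePoints = triple)
}
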