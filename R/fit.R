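# Weighted simultaneous fitting of the linked-equilibrium model to
# heterogeneous datasets (DSC at several K+ levels, CD melting at several
# K+ levels, ITC at several temperatures) with shared thermodynamic
# parameters and dataset-local nuisance parameters.

SHARED_NAMES <- c("UI.dG0", "UI.dH0", "UI.dCp", "UI.n",
                  "IQ.dG0", "IQ.dH0", "IQ.dCp", "IQ.n",
                  "s1.dG0", "s1.dH0", "s1.dCp",
                  "s2.dG0", "s2.dH0", "s2.dCp")

shared_from_model <- function(model) {
  t1 <- model$transitions[[1]]; t2 <- model$transitions[[2]]
  s1 <- model$sites[[1]]; s2 <- model$sites[[2]]
  stats::setNames(c(t1$dG0, t1$dH0, t1$dCp, t1$n,
                    t2$dG0, t2$dH0, t2$dCp, t2$n,
                    s1$dG0, s1$dH0, s1$dCp,
                    s2$dG0, s2$dH0, s2$dCp), SHARED_NAMES)
}

model_from_shared <- function(p, ref = ref_conditions()) {
  system_model(
    transitions = list(
      transition_thermo("U->I", p[["UI.dG0"]], p[["UI.dH0"]], p[["UI.dCp"]], p[["UI.n"]]),
      transition_thermo("I->Q", p[["IQ.dG0"]], p[["IQ.dH0"]], p[["IQ.dCp"]], p[["IQ.n"]])),
    sites = list(
      site_thermo(1, p[["s1.dG0"]], p[["s1.dH0"]], p[["s1.dCp"]]),
      site_thermo(2, p[["s2.dG0"]], p[["s2.dH0"]], p[["s2.dCp"]])),
    ref = ref)
}

shared_bounds <- function() {
  lower <- c(UI.dG0 = -12, UI.dH0 = -70, UI.dCp = -1, UI.n = -3,
             IQ.dG0 = -12, IQ.dH0 = -70, IQ.dCp = -1, IQ.n = -3,
             s1.dG0 = -14, s1.dH0 = -40, s1.dCp = -0.6,
             s2.dG0 = -14, s2.dH0 = -40, s2.dCp = -0.6)
  # site dCp is bounded above by zero: end-stacking binding buries surface
  # and sheds water, so a positive binding heat-capacity change is excluded
  # a priori (it also opens a spurious enthalpy-partitioning ridge between
  # the two sites in three-temperature ITC fits)
  upper <- c(UI.dG0 = 3, UI.dH0 = 10, UI.dCp = 0.5, UI.n = 0.5,
             IQ.dG0 = 3, IQ.dH0 = 10, IQ.dCp = 0.5, IQ.n = 0.5,
             s1.dG0 = -4, s1.dH0 = 5, s1.dCp = 0,
             s2.dG0 = -4, s2.dH0 = 5, s2.dCp = 0)
  list(lower = lower, upper = upper)
}

# data-driven starts and bounds for the dataset-local nuisance parameters
nuisance_table <- function(ds, i) {
  pre <- sprintf("d%d.", i)
  if (ds$kind == "DSC") {
    bl <- dsc_intrinsic_baseline(ds$data$temperature_C, ds$data$cp_kcal_mol_K)
    data.frame(name = paste0(pre, c("bl0", "bl1", "bl2")),
               start = bl$coef,
               lower = bl$coef - c(2, 0.05, 1e-3),
               upper = bl$coef + c(2, 0.05, 1e-3))
  } else if (ds$kind == "CD") {
    tc <- ds$data$temperature_C; y <- ds$data$ellipticity
    nlo <- tc <= stats::quantile(tc, 0.15)
    nhi <- tc >= stats::quantile(tc, 0.85)
    bQ <- unname(stats::coef(stats::lm(y[nlo] ~ tc[nlo])))
    bU <- unname(stats::coef(stats::lm(y[nhi] ~ tc[nhi])))
    rng <- diff(range(y))
    data.frame(name = paste0(pre, c("bQ0", "bQ1", "bU0", "bU1", "fI")),
               start = c(bQ, bU, 0.5),
               lower = c(bQ[1] - rng, bQ[2] - rng / 20,
                         bU[1] - rng, bU[2] - rng / 20, 0),
               upper = c(bQ[1] + rng, bQ[2] + rng / 20,
                         bU[1] + rng, bU[2] + rng / 20, 1))
  } else if (ds$kind == "ITC") {
    off <- stats::median(utils::tail(ds$data$heat_kcal_per_mol_DNA, 3))
    data.frame(name = paste0(pre, "offset"),
               start = off, lower = off - 4, upper = off + 4)
  } else {
    stop("datasets of kind SPECTRA are not fitted directly", call. = FALSE)
  }
}

#' Assemble a global fitting problem
#'
#' Builds the joint parameter table: the fourteen shared thermodynamic
#' parameters (two folding transitions, two binding sites) with fix/free
#' flags and finite box bounds, plus dataset-local nuisance parameters
#' (DSC intrinsic-baseline quadratic, CD baselines and the intermediate
#' coefficient fI, ITC dilution offset) with data-driven starting values.
#'
#' @param datasets list of [experiment_dataset()] objects of kinds DSC,
#'   CD and/or ITC.
#' @param model0 starting [system_model()]; its values seed the shared
#'   starts.
#' @param free character vector of shared parameter names to free (subset
#'   of `UI.dG0 ... s2.dCp`); nuisance parameters are always free.
#' @param weights `"invvar"` weights each dataset by 1 / (n * noise
#'   variance), with the variance estimated from first differences of the
#'   data, so that observables with different units contribute comparably;
#'   `"unit"` uses plain unweighted SSR.
#' @return An object of class `fit_problem`.
#' @export
fit_problem <- function(datasets, model0 = model_22gt(),
                        free = SHARED_NAMES,
                        weights = c("invvar", "unit")) {
  weights <- match.arg(weights)
  stopifnot(length(datasets) >= 1)
  bad <- setdiff(free, SHARED_NAMES)
  if (length(bad)) stop("unknown shared parameters: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  sb <- shared_bounds()
  tab <- data.frame(name = SHARED_NAMES,
                    start = unname(shared_from_model(model0)),
                    lower = unname(sb$lower), upper = unname(sb$upper),
                    free = SHARED_NAMES %in% free)
  for (i in seq_along(datasets)) {
    nt <- nuisance_table(datasets[[i]], i)
    nt$free <- TRUE
    tab <- rbind(tab, nt)
  }
  w <- vapply(seq_along(datasets), function(i) {
    y <- observed_vector(datasets[[i]])
    if (weights == "unit") return(1)
    v <- stats::var(diff(y)) / 2            # white-noise variance proxy
    1 / (length(y) * max(v, 1e-300))
  }, numeric(1))
  structure(list(datasets = datasets, table = tab, weights = w,
                 weightMode = weights, ref = model0$ref),
            class = "fit_problem")
}

observed_vector <- function(ds) {
  switch(ds$kind,
         DSC = ds$data$cp_kcal_mol_K,
         CD = ds$data$ellipticity,
         ITC = ds$data$heat_kcal_per_mol_DNA,
         stop("unsupported dataset kind: ", ds$kind, call. = FALSE))
}

#' Forward-model prediction for one dataset
#'
#' @param ds an [experiment_dataset()].
#' @param model a [system_model()].
#' @param nuisance named numeric vector of the dataset's nuisance
#'   parameters (unprefixed names, e.g. `bl0`, `fI`, `offset`).
#' @return Predicted observable vector on the dataset's grid.
#' @export
predict_dataset <- function(ds, model, nuisance) {
  if (ds$kind == "DSC") {
    tc <- ds$data$temperature_C
    nuisance[["bl0"]] + nuisance[["bl1"]] * tc + nuisance[["bl2"]] * tc^2 +
      dsc_excess_cp(model, tc, ds$conditions$cK)
  } else if (ds$kind == "CD") {
    cd_melting_curve(model, ds$data$temperature_C, ds$conditions$cK,
                     fI = nuisance[["fI"]],
                     baselineQ = c(nuisance[["bQ0"]], nuisance[["bQ1"]]),
                     baselineU = c(nuisance[["bU0"]], nuisance[["bU1"]]))
  } else if (ds$kind == "ITC") {
    itc_heats(model, ds$conditions$protocol, nuisance[["offset"]])
  } else {
    stop("unsupported dataset kind: ", ds$kind, call. = FALSE)
  }
}

split_params <- function(problem, p) {
  shared <- p[SHARED_NAMES]
  nuis <- lapply(seq_along(problem$datasets), function(i) {
    pre <- sprintf("d%d.", i)
    sel <- startsWith(names(p), pre)
    stats::setNames(p[sel], sub(pre, "", names(p)[sel], fixed = TRUE))
  })
  list(shared = shared, nuisance = nuis)
}

# weighted residual vector over all datasets; forward-model failures map
# to a large finite penalty so the optimizer can back away
residual_vector <- function(problem, p) {
  sp <- split_params(problem, p)
  model <- model_from_shared(sp$shared, problem$ref)
  unlist(lapply(seq_along(problem$datasets), function(i) {
    ds <- problem$datasets[[i]]
    y <- observed_vector(ds)
    yhat <- tryCatch(predict_dataset(ds, model, sp$nuisance[[i]]),
                     error = function(e) rep(NA_real_, length(y)))
    r <- sqrt(problem$weights[i]) * (y - yhat)
    r[!is.finite(r)] <- 1e6
    r
  }))
}

#' Weighted global objective
#'
#' `SSR = sum_d w_d sum_i (y_di - yhat_di)^2` with the problem's dataset
#' weights.
#'
#' @param problem a [fit_problem()].
#' @param p full named parameter vector (shared + nuisance).
#' @return The weighted sum of squared residuals.
#' @export
objective <- function(problem, p) {
  sum(residual_vector(problem, p)^2)
}

full_param_vector <- function(problem, pfree) {
  p <- stats::setNames(problem$table$start, problem$table$name)
  p[names(pfree)] <- pfree
  p
}

#' Multi-start bounded global fit
#'
#' Fits all free parameters jointly by bounded Levenberg-Marquardt least
#' squares ([minpack.lm::nls.lm]) from `nStarts` starting points: the
#' nominal start (data-driven nuisance values, `model0` shared values)
#' plus Latin-hypercube draws of the free shared parameters over their
#' bounds.  The best local solution is returned.  Deterministic given
#' `seed`.
#'
#' @param problem a [fit_problem()].
#' @param nStarts number of starts (default 20).
#' @param seed RNG seed (mandatory).
#' @return An object of class `fit_result`: `estimates` (full named
#'   parameter vector), `model` (the fitted [system_model()]),
#'   `nuisance` (per dataset), `objective` (weighted SSR), `residuals`
#'   (per dataset, unweighted), `restarts` (per-start objective log) and
#'   `seed`.
#' @export
fit_global <- function(problem, nStarts = 20, seed) {
  stopifnot(inherits(problem, "fit_problem"), !missing(seed))
  tab <- problem$table
  freeTab <- tab[tab$free, ]
  nfree <- nrow(freeTab)
  lower <- stats::setNames(freeTab$lower, freeTab$name)
  upper <- stats::setNames(freeTab$upper, freeTab$name)

  starts <- matrix(freeTab$start, nrow = 1,
                   dimnames = list(NULL, freeTab$name))
  if (nStarts > 1) {
    sharedFree <- intersect(freeTab$name, SHARED_NAMES)
    set.seed(seed)
    extra <- matrix(rep(freeTab$start, each = nStarts - 1),
                    nrow = nStarts - 1, dimnames = list(NULL, freeTab$name))
    if (length(sharedFree)) {
      u <- lhs::randomLHS(nStarts - 1, length(sharedFree))
      for (j in seq_along(sharedFree)) {
        nm <- sharedFree[j]
        extra[, nm] <- lower[nm] + u[, j] * (upper[nm] - lower[nm])
      }
    }
    starts <- rbind(starts, extra)
  }

  runs <- vector("list", nrow(starts))
  for (s in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(starts[s, ], lower), upper)
    runs[[s]] <- tryCatch({
      fit <- minpack.lm::nls.lm(
        par = p0,
        lower = lower, upper = upper,
        fn = function(q) residual_vector(problem, full_param_vector(
          problem, stats::setNames(q, freeTab$name))),
        control = minpack.lm::nls.lm.control(maxiter = 200, ptol = 1e-10,
                                             ftol = 1e-10))
      list(par = stats::setNames(coef(fit), freeTab$name),
           objective = fit$deviance, converged = fit$info %in% 1:4,
           message = fit$message)
    }, error = function(e) list(par = NULL, objective = Inf,
                                converged = FALSE,
                                message = conditionMessage(e)))
  }
  objs <- vapply(runs, `[[`, numeric(1), "objective")
  if (all(!is.finite(objs))) {
    stop("all starts failed: ",
         paste(unique(vapply(runs, `[[`, character(1), "message")),
               collapse = "; "), call. = FALSE)
  }
  best <- runs[[which.min(objs)]]
  p <- full_param_vector(problem, best$par)
  sp <- split_params(problem, p)
  model <- model_from_shared(sp$shared, problem$ref)
  residuals <- lapply(seq_along(problem$datasets), function(i) {
    ds <- problem$datasets[[i]]
    observed_vector(ds) - predict_dataset(ds, model, sp$nuisance[[i]])
  })
  structure(list(estimates = p, model = model, nuisance = sp$nuisance,
                 objective = sum(residual_vector(problem, p)^2),
                 residuals = residuals,
                 restarts = data.frame(start = seq_along(objs),
                                       objective = objs,
                                       converged = vapply(runs, `[[`,
                                                          logical(1), "converged")),
                 freeNames = freeTab$name, seed = seed,
                 problem = problem),
            class = "fit_result")
}

#' Residual-bootstrap parameter uncertainties
#'
#' Resamples each dataset's fitted residuals with replacement, refits
#' from the solution (single start), and reports the standard deviation
#' of the bootstrap estimates per free parameter.  Deterministic given
#' `seed`.
#'
#' @param problem a [fit_problem()].
#' @param result a converged [fit_global()] result.
#' @param nBoot number of bootstrap replicates.
#' @param seed RNG seed.
#' @return Named vector of standard errors for the free parameters; a
#'   warning is issued (and the spread is still reported) if fewer than
#'   half the replicates converge.
#' @export
estimate_uncertainty <- function(problem, result, nBoot = 50, seed) {
  stopifnot(!missing(seed))
  sp <- split_params(problem, result$estimates)
  fitted <- lapply(seq_along(problem$datasets), function(i) {
    predict_dataset(problem$datasets[[i]], result$model, sp$nuisance[[i]])
  })
  set.seed(seed)
  boots <- matrix(NA_real_, nBoot, length(result$freeNames),
                  dimnames = list(NULL, result$freeNames))
  ok <- logical(nBoot)
  for (b in seq_len(nBoot)) {
    bootProblem <- problem
    for (i in seq_along(problem$datasets)) {
      r <- result$residuals[[i]]
      ystar <- fitted[[i]] + sample(r, length(r), replace = TRUE)
      ds <- bootProblem$datasets[[i]]
      ds$data[[switch(ds$kind, DSC = "cp_kcal_mol_K", CD = "ellipticity",
                      ITC = "heat_kcal_per_mol_DNA")]] <- ystar
      bootProblem$datasets[[i]] <- ds
    }
    bootProblem$table$start[match(result$freeNames, bootProblem$table$name)] <-
      result$estimates[result$freeNames]
    fit <- tryCatch(fit_global(bootProblem, nStarts = 1, seed = seed + b),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      boots[b, ] <- fit$estimates[result$freeNames]
      ok[b] <- TRUE
    }
  }
  if (mean(ok) < 0.5) {
    warning("fewer than half of the bootstrap refits converged; intervals are unreliable")
  }
  apply(boots[ok, , drop = FALSE], 2, stats::sd)
}
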