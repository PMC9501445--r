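# helper: full parameter vector holding the generating truth for a problem
# built from synthetic datasets
truth_vector <- function(problem, scenario) {
  p <- stats::setNames(problem$table$start, problem$table$name)
  p[SHARED_NAMES_TEST] <- quadlink:::shared_from_model(scenario$model)
  for (i in seq_along(problem$datasets)) {
    ds <- problem$datasets[[i]]
    pre <- sprintf("d%d.", i)
    if (ds$kind == "DSC") {
      p[paste0(pre, c("bl0", "bl1", "bl2"))] <- ds$truth$intrinsic
    } else if (ds$kind == "CD") {
      p[paste0(pre, c("bQ0", "bQ1"))] <- ds$truth$baselineQ
      p[paste0(pre, c("bU0", "bU1"))] <- ds$truth$baselineU
      p[paste0(pre, "fI")] <- ds$truth$fI
    } else if (ds$kind == "ITC") {
      p[paste0(pre, "offset")] <- ds$truth$dilutionOffset
    }
  }
  p
}
SHARED_NAMES_TEST <- c("UI.dG0", "UI.dH0", "UI.dCp", "UI.n",
                       "IQ.dG0", "IQ.dH0", "IQ.dCp", "IQ.n",
                       "s1.dG0", "s1.dH0", "s1.dCp",
                       "s2.dG0", "s2.dH0", "s2.dCp")

test_that("objective vanishes at truth on noiseless data and grows away from it", {
  sc <- scenario_spec(seed = 2, dsc = list(sigma = 0, tempC = seq(0.5, 95, 1)),
                      cd = list(sigmaRel = 0, tempC = seq(5, 95, 2)),
                      itc = list(sigma = 0, tempC = 25))
  datasets <- c(make_dsc(sc)[2:3], make_cd(sc)$curves[2:3], make_itc(sc))
  prob <- fit_problem(datasets, weights = "unit")
  p <- truth_vector(prob, sc)
  expect_lt(objective(prob, p), 1e-10)
  for (nm in c("UI.dH0", "IQ.dG0", "s2.dH0")) {
    q <- p; q[nm] <- q[nm] + 0.5
    expect_gt(objective(prob, q), objective(prob, p))
  }
})

test_that("inverse-variance weighting balances heterogeneous observables", {
  sc <- small_scenario(seed = 3)
  datasets <- c(make_dsc(sc)[3], make_cd(sc)$curves[3])
  probW <- fit_problem(datasets, weights = "invvar")
  probU <- fit_problem(datasets, weights = "unit")
  expect_identical(probU$weights, c(1, 1))
  p <- truth_vector(probW, sc)
  # per-dataset weighted residual magnitudes are comparable despite the
  # ~1e9 gap in raw units between heat capacity and raw ellipticity
  r <- lapply(seq_along(datasets), function(i) {
    y <- quadlink:::observed_vector(datasets[[i]])
    sp <- quadlink:::split_params(probW, p)
    yhat <- predict_dataset(datasets[[i]], sc$model, sp$nuisance[[i]])
    probW$weights[i] * sum((y - yhat)^2)
  })
  expect_lt(max(unlist(r)) / min(unlist(r)), 20)
})

test_that("fitting noiseless folding data recovers truth to high precision", {
  sc <- scenario_spec(seed = 2, dsc = list(sigma = 0, tempC = seq(0.5, 95, 1),
                                           cK = c(0.001, 0.1)),
                      cd = list(sigmaRel = 0, tempC = seq(5, 95, 2),
                                cK = c(0.001, 0.1)))
  datasets <- c(make_dsc(sc), make_cd(sc)$curves)
  prob <- fit_problem(datasets,
                      free = c("UI.dG0", "UI.dH0", "UI.n", "IQ.dG0", "IQ.dH0", "IQ.n"))
  # single start from the data-driven nominal: perturb the shared starts
  prob$table$start[prob$table$name == "UI.dH0"] <- -30
  prob$table$start[prob$table$name == "IQ.dH0"] <- -26
  fit <- fit_global(prob, nStarts = 1, seed = 1)
  truth <- quadlink:::shared_from_model(model_22gt())
  for (nm in c("UI.dG0", "UI.dH0", "UI.n", "IQ.dG0", "IQ.dH0", "IQ.n")) {
    expect_equal(fit$estimates[[nm]], truth[[nm]], tolerance = 1e-4)
  }
  expect_equal(fit$objective,
               sum(quadlink:::residual_vector(prob, fit$estimates)^2),
               tolerance = 1e-9)
})

test_that("refitting from a solution reproduces the solution", {
  sc <- small_scenario(seed = 5)
  datasets <- make_cd(sc)$curves[c(1, 3)]
  prob <- fit_problem(datasets, free = c("UI.dG0", "UI.dH0", "UI.n"))
  fit1 <- fit_global(prob, nStarts = 1, seed = 1)
  prob2 <- prob
  prob2$table$start[match(fit1$freeNames, prob2$table$name)] <-
    fit1$estimates[fit1$freeNames]
  fit2 <- fit_global(prob2, nStarts = 1, seed = 1)
  expect_equal(fit2$estimates, fit1$estimates, tolerance = 1e-6)
  expect_lte(fit2$objective, fit1$objective * (1 + 1e-8))
})

test_that("fits are deterministic given the seed", {
  sc <- small_scenario(seed = 5)
  datasets <- make_cd(sc)$curves[2]
  prob <- fit_problem(datasets, free = c("UI.dG0", "UI.dH0"))
  f1 <- fit_global(prob, nStarts = 3, seed = 7)
  f2 <- fit_global(prob, nStarts = 3, seed = 7)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$restarts, f2$restarts)
})

test_that("bootstrap uncertainties are near zero without noise and grow with it", {
  base <- list(sigmaRel = 0, tempC = seq(5, 95, 2), cK = 0.01)
  mk <- function(noise, seed) {
    b <- base; b$sigmaRel <- noise
    make_cd(scenario_spec(seed = seed, cd = b))$curves
  }
  fitFor <- function(noise) {
    prob <- fit_problem(mk(noise, 11), free = c("UI.dG0", "UI.dH0"))
    fit <- fit_global(prob, nStarts = 1, seed = 2)
    estimate_uncertainty(prob, fit, nBoot = 12, seed = 3)
  }
  se0 <- fitFor(0)
  expect_lt(se0[["UI.dH0"]], 1e-3)
  se1 <- fitFor(0.01)
  se2 <- fitFor(0.04)
  expect_gt(se2[["UI.dH0"]], se1[["UI.dH0"]])
})

test_that("objective at the fitted solution beats the truth on noisy data", {
  sc <- scenario_spec(seed = 17, cd = list(tempC = seq(5, 95, 2)))
  datasets <- make_cd(sc)$curves[2]
  prob <- fit_problem(datasets, free = c("UI.dG0", "UI.dH0", "UI.n"))
  fit <- fit_global(prob, nStarts = 1, seed = 1)
  p <- truth_vector(prob, sc)
  expect_lte(fit$objective, objective(prob, p))
})

test_that("mechanism comparison prefers the generating linked mechanism", {
  sc <- scenario_spec(seed = 6)
  itc <- make_itc(sc)
  tab <- compare_mechanisms(itc, nStarts = 6, seed = 2)
  expect_identical(tab$mechanism[1], "linked_equilibrium")
  expect_identical(nrow(tab), 3L)
  # single mechanism: table of one row
  tab1 <- compare_mechanisms(itc[2], mechanisms = "sequential", nStarts = 2,
                             seed = 1)
  expect_identical(nrow(tab1), 1L)
})

test_that("simple 1:1 data do not reward the more elaborate mechanism", {
  # generate isotherms under plain one-site binding to the folded form
  proto <- itc_protocol(tempC = 25)
  # second binding step switched off (weak dG -4 => negligible occupancy)
  heats <- quadlink:::mechanism_predict("sequential",
                                        c(-9.6, -18, 0, -1, 0, 0, -0.3),
                                        list(experiment_dataset("ITC",
                                          data.frame(injection_index = 1:25,
                                                     volume_uL = rep(10, 25),
                                                     heat_kcal_per_mol_DNA = 0),
                                          conditions = list(protocol = proto))),
                                        ref_conditions())[[1]]
  set.seed(31)
  ds <- experiment_dataset("ITC",
                           data.frame(injection_index = 1:25,
                                      volume_uL = rep(10, 25),
                                      heat_kcal_per_mol_DNA = heats + rnorm(25, sd = 0.2)),
                           conditions = list(protocol = proto))
  tab <- compare_mechanisms(list(ds),
                            mechanisms = c("sequential", "linked_equilibrium"),
                            nStarts = 8, seed = 5)
  aicc <- stats::setNames(tab$aicc, tab$mechanism)
  expect_lte(aicc[["sequential"]], aicc[["linked_equilibrium"]] + 2)
})
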