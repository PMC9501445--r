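# Small model fixtures built in code.

# effectively two-state U <-> Q model: the intermediate is lifted far above
# both end states so it never populates
two_state_model <- function(dG_UQ = -5.7, dH_UQ = -60) {
  system_model(
    list(transition_thermo("U->I", 20, 0, 0, 0),
         transition_thermo("I->Q", dG_UQ - 20, dH_UQ, 0, 0)),
    list(site_thermo(1, -9.6, -18, 0), site_thermo(2, -8.7, -20, 0)))
}

# model with ligand binding switched off (both sites strongly unfavorable)
no_binding_model <- function(base = model_22gt()) {
  system_model(base$transitions,
               list(site_thermo(1, 20, 0, 0), site_thermo(2, 20, 0, 0)),
               base$ref)
}

# reduced-size scenario for fast unit tests (coarser grids, fewer levels)
small_scenario <- function(seed = 1, ...) {
  scenario_spec(seed = seed,
                dsc = list(tempC = seq(0.5, 95, by = 1)),
                cd = list(tempC = seq(5, 95, by = 2)),
                itc = list(tempC = c(25)),
                ...)
}
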