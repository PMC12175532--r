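# Toy enzyme used across the kinetics tests: kcat_C = 2, K_C = 10 uM,
# K_O = 100 uM, S_C/O = 10, so the derived kcat_O is also 2.
toyParams <- function() kineticParams("toy", kcat_C = 2, K_C = 10,
                                      K_O = 100, S_CO = 10)

# Temperature model with chosen enthalpies around the toy enzyme.
toyModel <- function(dh = c(kcat_C = 50, K_C = 30, K_O = 15, kcat_O = 40)) {
  buildTemperatureModel(toyParams(), dh)
}

examplesKineticsPath <- function() {
  system.file("extdata", "example_kinetics.tsv", package = "RubiscoTherm")
}

# Small cohort shared by scoring/acceptance tests (cached per session).
.cohortCache <- new.env(parent = emptyenv())
cachedCohort <- function(seed = 1, effect_size = 0.03) {
  key <- sprintf("s%d_e%g", seed, effect_size)
  if (is.null(.cohortCache[[key]]))
    .cohortCache[[key]] <- generateCohort(seed = seed,
                                          effect_size = effect_size)
  .cohortCache[[key]]
}
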