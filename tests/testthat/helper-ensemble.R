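# The full-scale fixture ensemble (N = 4096, both conditions) is the
# heaviest computation in the suite; several test files interrogate it, so
# it is simulated once per test run and cached here.
.ensembleCache <- new.env(parent = emptyenv())

fixtureEnsemble <- function(N = 4096L) {
  key <- paste0("N", N)
  if (is.null(.ensembleCache[[key]])) {
    model <- makeReducedErbbModel()
    space <- reducedErbbSpace()
    samples <- sobolSample(space, N)
    tab <- runEnsemble(model, samples, modelConditions(model),
                       modelReadouts(model))
    tab <- plausibilityFilter(tab, threshold = 0.01,
                              reference_condition = "no_drug")
    .ensembleCache[[key]] <- list(model = model, space = space,
                                  samples = samples, table = tab)
  }
  .ensembleCache[[key]]
}
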