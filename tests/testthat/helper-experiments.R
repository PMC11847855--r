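# Shared experiment runs for the acceptance tests (computed once, cached
# for the duration of the test run).

.exp_cache <- new.env(parent = emptyenv())

desk_experiment <- function(example, ploidy, allelism, seed, reps = 5) {
  key <- paste(example, ploidy, allelism, seed, reps, sep = "_")
  if (!is.null(.exp_cache[[key]])) return(.exp_cache[[key]])
  cfg <- exampleConfig(example, ploidy, allelism, scale = "desk")
  res <- replicateExperiment(cfg, nFounderReps = reps, seed = seed)
  .exp_cache[[key]] <- res$replicates
  res$replicates
}

# miniature full-model experiment for comparing prediction models on the
# same founder replicates (identical seeds pair the runs)
mini_model_experiment <- function(model, seed, reps = 3) {
  key <- paste("mini", model, seed, reps, sep = "_")
  if (!is.null(.exp_cache[[key]])) return(.exp_cache[[key]])
  cfg <- breedingConfig(
    ploidy = 2L,
    trait = TraitModel(varA = 1, varD = 0.25, varAA = 0.25, varAD = 0.25,
                       varDD = 0.25, varE = 2),
    genome = list(chromLengths = rep(888.6 / 12, 12), markerPool = 2500L,
                  qtlPool = 1200L, qtlAlleles = 2L, Ne = 200L,
                  nGenerations = 1000L,
                  bottleneck = list(from = 901L, to = 950L, Ne = 100L),
                  mutationRate = 2.5e-3, nFounders = 100L, nQtl = 600L,
                  nMarkers = 1500L, mafMin = 0.05,
                  allelismProfile = data.frame(alleles = 2, proportion = 1)),
    nParents = 20L, nFamilies = 20L, familySize = 10L,
    nGenerations = 13L, randomUntil = 5L, remlAt = 6L,
    selectionModel = model, nEpistaticPairs = 300L, gainOn = "g")
  res <- replicateExperiment(cfg, nFounderReps = reps, seed = seed)
  .exp_cache[[key]] <- res$replicates
  res$replicates
}
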