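#' Pseudo-random crossing plan with contribution caps
#'
#' Draws exactly \code{nFamilies} parent pairs such that no parent mates
#' itself (when \code{noSelfing}) and no parent appears in more than
#' \code{maxContrib} crosses. Sampling is rejection-based with local repair:
#' parents are replicated up to the cap, shuffled, paired, and self-pairs
#' are resolved by swapping partners between families.
#'
#' @param parents vector of parent ids.
#' @param nFamilies number of crosses.
#' @param maxContrib maximum crosses per parent (default 4).
#' @param noSelfing forbid identical pair members (default TRUE).
#' @param maxTries resampling attempts before giving up.
#' @return data.frame with columns mother, father (one row per family).
#' @export
makeCrosses <- function(parents, nFamilies, maxContrib = 4L,
                        noSelfing = TRUE, maxTries = 1000L) {
  P <- length(parents)
  if (2L * nFamilies > maxContrib * P)
    stop(sprintf("infeasible crossing plan: 2*%d families > %d*%d parents",
                 nFamilies, maxContrib, P))
  if (noSelfing && P < 2L) stop("no-selfing requires at least 2 parents")
  for (try in seq_len(maxTries)) {
    pool <- sample(rep(parents, maxContrib))[seq_len(2L * nFamilies)]
    pairs <- matrix(pool, nrow = 2L)
    if (!noSelfing) return(data.frame(mother = pairs[1, ],
                                      father = pairs[2, ]))
    ok <- FALSE
    for (pass in 1:20) {
      selfs <- which(pairs[1, ] == pairs[2, ])
      if (!length(selfs)) { ok <- TRUE; break }
      if (nFamilies < 2L) break
      for (i in selfs) {
        j <- sample(setdiff(seq_len(nFamilies), i), 1L)
        if (pairs[2, j] != pairs[1, i] && pairs[2, i] != pairs[1, j]) {
          tmp <- pairs[2, i]; pairs[2, i] <- pairs[2, j]; pairs[2, j] <- tmp
        }
      }
    }
    if (ok) return(data.frame(mother = pairs[1, ], father = pairs[2, ]))
  }
  stop("could not draw a crossing plan satisfying the constraints")
}

#' Produce one generation of offspring with genetic values and phenotypes
#'
#' Each offspring is the union of one gamete from each listed parent
#' (bivalent-pairing meiosis); every family contributes \code{familySize}
#' full sibs. All offspring are genotyped and phenotyped.
#'
#' @param parents a \linkS4class{GenomePopulation} of the crossing parents.
#' @param crossPlan data.frame with columns mother, father holding positions
#'   (1..nInd(parents)) or parent ids (see \code{byId}).
#' @param familySize full sibs per family.
#' @param panel,effects,trait panel, effect set and trait model of the
#'   simulation.
#' @param generation integer label for the offspring.
#' @param idStart first offspring id minus one (default: continue after the
#'   largest parent id).
#' @param byId interpret crossPlan entries as parent ids rather than
#'   positions.
#' @return list(pop, gv, y)
#' @export
advanceGeneration <- function(parents, crossPlan, familySize, panel, effects,
                              trait, generation = 1L, idStart = NULL,
                              byId = FALSE) {
  if (is.null(idStart)) idStart <- max(parents@id)
  mi <- mapIndex(parents@map)
  mpos <- crossPlan$mother; fpos <- crossPlan$father
  if (byId) {
    mpos <- match(mpos, parents@id); fpos <- match(fpos, parents@id)
  }
  mrep <- rep(mpos, each = familySize); frep <- rep(fpos, each = familySize)
  H <- cpp_offspring(parents@haplotypes, parents@ploidy,
                     as.integer(mrep) - 1L, as.integer(frep) - 1L,
                     mi$chrStart, mi$chrEnd, mi$posM, mi$chrLenM)
  nOff <- length(mrep)
  pop <- GenomePopulation(parents@map, parents@ploidy, H,
                          id = idStart + seq_len(nOff),
                          mother = parents@id[mrep],
                          father = parents@id[frep],
                          generation = rep(as.integer(generation), nOff))
  gv <- geneticValues(pop, panel, effects)
  y <- simulatePhenotypes(gv, 0, trait@varE)
  list(pop = pop, gv = gv, y = y)
}

#' Select parents at random or by predicted breeding value
#'
#' @param candidates candidate ids (in stable id order).
#' @param criterion "random" (uniform without replacement) or "ebv" (top n,
#'   ties broken by position in \code{candidates}).
#' @param ebv predicted breeding values aligned with candidates (required
#'   for criterion "ebv").
#' @param n number to select.
#' @return selected ids
#' @export
selectParents <- function(candidates, criterion = c("random", "ebv"),
                          ebv = NULL, n) {
  criterion <- match.arg(criterion)
  if (n > length(candidates)) stop("cannot select more than available")
  if (criterion == "random") return(sample(candidates, n))
  if (is.null(ebv)) stop("criterion 'ebv' requires predicted breeding values")
  ord <- order(-ebv, seq_along(candidates))
  candidates[ord[seq_len(n)]]
}

#' Accuracy of prediction
#'
#' Pearson correlation between true and predicted breeding values of the
#' same individuals; NA with a warning when either vector is constant.
#'
#' @param trueU,predU numeric vectors over the same individuals.
#' @return numeric correlation
#' @export
accuracy <- function(trueU, predU) {
  if (stats::sd(trueU) == 0 || stats::sd(predU) == 0) {
    warning("zero variance: accuracy undefined")
    return(NA_real_)
  }
  stats::cor(trueU, predU)
}

#' Rate of genetic gain
#'
#' (mean at the end generation - mean at the start generation) divided by
#' the number of generations between them (8 for the default scheme,
#' generations 5 to 13).
#'
#' @param meanStart,meanEnd genetic means of the population.
#' @param generations generations elapsed (default 8).
#' @return numeric gain per generation
#' @export
rateOfGain <- function(meanStart, meanEnd, generations = 8) {
  (meanEnd - meanStart) / generations
}

# Marker-space (ridge) GBLUP, exactly equivalent to the G-based solve with
# Gu = W W' / c and variance sigmaU2: solve the augmented normal equations
# [X'X  X'W ] [b]   [X'y]
# [W'X  W'W + lambda I] [alpha] = [W'y],  lambda = sigmaE2 / (sigmaU2 / c),
# and return alpha with the centering frequencies, so ebv_i = w_i' alpha.
# W'W etc. are assembled from incrementally maintained statistics of the raw
# dosage matrix T: TtT = T'T, s = colSums(T), Ty = T'y, per-generation
# column sums and record counts.
snpBlupSolve <- function(TtT, s, Ty, genCS, genN, genSumY, n, k, p,
                         sigmaU2, sigmaE2) {
  m <- length(s)
  cScale <- k * sum(p * (1 - p))
  lambda <- sigmaE2 / (sigmaU2 / cScale)
  # -k s p' - k p s' + n k^2 p p' written as u p' + p u' to halve the outers
  u <- -k * s + (n * k^2 / 2) * p
  WtW <- TtT + outer(u, p) + outer(p, u)
  dix <- seq.int(1L, m * m, by = m + 1L)
  WtW[dix] <- WtW[dix] + lambda
  XtW <- genCS - k * genN %o% p         # nGenLevels x m
  Wty <- Ty - k * p * sum(genSumY)
  ng <- length(genN)
  A <- matrix(0, ng + m, ng + m)
  A[seq_len(ng), seq_len(ng)] <- diag(genN, ng)
  A[seq_len(ng), ng + seq_len(m)] <- XtW
  A[ng + seq_len(m), seq_len(ng)] <- t(XtW)
  A[ng + seq_len(m), ng + seq_len(m)] <- WtW
  rhs <- c(genSumY, Wty)
  ch <- chol(A)
  sol <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
  list(b = sol[seq_len(ng)], alpha = sol[ng + seq_len(m)], p = p)
}

#' Run one breeding-scheme replicate
#'
#' Executes the configured number of discrete generations from a founder
#' population: pseudo-random crossing with contribution caps, full-sib
#' families, phenotyping of every offspring, random parent selection in the
#' early phase, a one-time REML variance-component estimation at the
#' configured generation on all phenotypes accumulated before it, and GBLUP
#' truncation selection on predicted breeding values thereafter. All
#' phenotypes and genotypes from generation 1 up to the current generation
#' enter each evaluation; generation is the only fixed effect. Selection is
#' always on the additive BLUP, whichever prediction model is fitted. If a
#' non-additive REML fit does not converge, the scheme falls back to the
#' additive-only model (logged in the details).
#'
#' @param config a \linkS4class{BreedingConfig}.
#' @param founders founder \linkS4class{GenomePopulation} (generation 0).
#' @param panel a \linkS4class{LociPanel}.
#' @param effects an \linkS4class{EffectSet}.
#' @param seed optional integer seed.
#' @return a \linkS4class{Trajectory}
#' @export
runBreedingScheme <- function(config, founders, panel, effects, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- config@ploidy
  off <- config@nFamilies * config@familySize
  nGen <- config@nGenerations
  mk <- panel@markers
  m <- length(mk)
  trait <- config@trait
  model <- config@selectionModel

  gv0 <- geneticValues(founders, panel, effects)
  stats <- data.frame(generation = 0L, meanU = mean(gv0@a),
                      varU = stats::var(gv0@a), meanG = mean(gv0@g),
                      varG = stats::var(gv0@g), meanY = NA_real_)

  N <- nGen * off
  M <- matrix(0L, N, m)          # counted-allele marker dosages, records
  TtT <- matrix(0, m, m)         # running T'T
  sCol <- numeric(m)             # running colSums(T)
  Ty <- numeric(m)               # running T'y
  genCS <- matrix(0, nGen, m)    # per-generation colSums(T)
  genN <- numeric(nGen); genSumY <- numeric(nGen)
  y <- numeric(N); genLab <- integer(N)
  uAll <- numeric(N); gAll <- numeric(N)
  nRec <- 0L

  parents <- founders[sample.int(nInd(founders), config@nParents)]
  acc <- NA_real_
  varcompUsed <- NULL
  details <- list(selectionModel = model, remlConverged = NA,
                  remlIterations = NA_integer_, fallback = FALSE)

  for (t in seq_len(nGen)) {
    plan <- makeCrosses(seq_len(nInd(parents)), config@nFamilies,
                        config@maxContrib, config@noSelfing)
    gen <- advanceGeneration(parents, plan, config@familySize, panel,
                             effects, trait, generation = t,
                             idStart = nInd(founders) + nRec)
    rows <- nRec + seq_len(off)
    Mnew <- markerDosage(gen$pop, mk)
    M[rows, ] <- Mnew
    Tnew <- matrix(as.numeric(Mnew), off, m)
    TtT <- TtT + crossprod(Tnew)
    cs <- colSums(Tnew)
    sCol <- sCol + cs
    Ty <- Ty + as.vector(crossprod(Tnew, gen$y))
    genCS[t, ] <- cs; genN[t] <- off; genSumY[t] <- sum(gen$y)
    y[rows] <- gen$y; genLab[rows] <- t
    uAll[rows] <- gen$gv@a; gAll[rows] <- gen$gv@g
    nRec <- nRec + off
    stats <- rbind(stats, data.frame(generation = t, meanU = mean(gen$gv@a),
                                     varU = stats::var(gen$gv@a),
                                     meanG = mean(gen$gv@g),
                                     varG = stats::var(gen$gv@g),
                                     meanY = mean(gen$y)))

    if (t == nGen) break
    if (t <= config@randomUntil) {
      sel <- selectParents(seq_len(off), "random", n = config@nParents)
    } else {
      idx <- seq_len(nRec)
      p <- sCol / (k * nRec)
      cand <- (nRec - off) + seq_len(off)
      if (t == config@remlAt) {
        # one-time variance-component estimation on the records accumulated
        # before this generation
        nR <- (config@remlAt - 1L) * off
        ridx <- seq_len(nR)
        pR <- colMeans(M[ridx, , drop = FALSE]) / k
        Gu <- additiveGRM(M[ridx, , drop = FALSE], k, freq = pR)
        gix <- seq.int(1L, nR * nR, by = nR + 1L)
        Gu[gix] <- Gu[gix] + 1e-6
        grmsR <- list(u = Gu)
        if (model != "additive") {
          Gv <- dominanceGRM(M[ridx, , drop = FALSE], k, freq = pR)
          diag(Gv) <- diag(Gv) + 1e-6
          grmsR$v <- Gv
          if (model == "additive_dominance_epistasis") {
            grmsR$uu <- Gu * Gu; grmsR$uv <- Gu * Gv; grmsR$vv <- Gv * Gv
          }
        }
        fit <- tryCatch(remlEstimate(y[ridx], genLab[ridx], grmsR),
                        error = function(e) NULL)
        if ((is.null(fit) || !fit@converged) && model != "additive") {
          details$fallback <- TRUE
          fit <- tryCatch(remlEstimate(y[ridx], genLab[ridx], grmsR["u"]),
                          error = function(e) NULL)
        }
        if (is.null(fit)) {
          varcompUsed <- c(u = trait@varA, e = trait@varE)
        } else {
          varcompUsed <- fit@varcomp
          details$remlConverged <- fit@converged
          details$remlIterations <- fit@iterations
        }
        details$varcomp <- varcompUsed
      }
      useDense <- details$fallback == FALSE && model != "additive" &&
        all(c("v") %in% names(varcompUsed))
      if (!useDense) {
        # additive model: equivalent marker-space ridge solve
        sol <- snpBlupSolve(TtT, sCol, Ty, genCS[seq_len(t), , drop = FALSE],
                            genN[seq_len(t)], genSumY[seq_len(t)], nRec, k,
                            p, varcompUsed[["u"]], varcompUsed[["e"]])
        ebvCand <- as.vector(Tnew %*% sol$alpha) - k * sum(p * sol$alpha)
      } else {
        # dominance/epistatic prediction models need the dense G solve
        pAll <- p
        Gu <- additiveGRM(M[idx, , drop = FALSE], k, freq = pAll)
        diag(Gu) <- diag(Gu) + 1e-6
        grms <- list(u = Gu)
        Gv <- dominanceGRM(M[idx, , drop = FALSE], k, freq = pAll)
        diag(Gv) <- diag(Gv) + 1e-6
        grms$v <- Gv
        if (model == "additive_dominance_epistasis") {
          grms$uu <- Gu * Gu; grms$uv <- Gu * Gv; grms$vv <- Gv * Gv
        }
        use <- intersect(names(grms), names(varcompUsed))
        pred <- solveGBLUP(y[idx], genLab[idx], grms[use],
                           varcompUsed[use], varcompUsed[["e"]])
        ebvCand <- pred@random$u[cand]
      }
      if (t == config@remlAt) acc <- accuracy(uAll[cand], ebvCand)
      sel <- selectParents(seq_len(off), "ebv", ebv = ebvCand,
                           n = config@nParents)
    }
    parents <- gen$pop[sort(sel)]
  }

  tr <- if (config@gainOn == "u") stats$meanU else stats$meanG
  gain <- rateOfGain(tr[stats$generation == config@randomUntil],
                     tr[stats$generation == nGen],
                     nGen - config@randomUntil)
  new("Trajectory", stats = stats, accuracy = acc, gain = gain,
      details = details)
}

#' @export
setMethod("show", "Trajectory", function(object) {
  cat("Trajectory over", max(object@stats$generation), "generations;",
      "accuracy =", signif(object@accuracy, 3), ", gain =",
      signif(object@gain, 4), "per generation\n")
})

#' Simulate a founder genome: map, historical population, founders, panel
#'
#' Builds the candidate-locus map, runs the Fisher-Wright historical
#' simulation, draws the founder individuals and selects the QTL/marker
#' panels under the configured MAF and allelism constraints.
#'
#' @param config a \linkS4class{BreedingConfig}.
#' @return list(founders, panel, map)
#' @export
simulateFounderGenome <- function(config) {
  g <- config@genome
  pools <- data.frame(pool = c("marker", "qtl"),
                      n = c(g$markerPool, g$qtlPool),
                      nAlleles = c(2L, g$qtlAlleles))
  map <- sampleGeneticMap(g$chromLengths, pools)
  hist <- simulateHistoricalPopulation(map, Ne = g$Ne,
                                       nGenerations = g$nGenerations,
                                       ploidy = config@ploidy,
                                       bottleneck = g$bottleneck,
                                       mutationRate = g$mutationRate)
  founders <- sampleFounders(hist, g$nFounders)
  panel <- selectLoci(founders, g$nQtl, g$nMarkers, g$mafMin,
                      g$allelismProfile)
  list(founders = founders, panel = panel, map = map)
}

#' Construct a BreedingConfig
#'
#' Defaults follow the reference breeding scheme: 80 parents crossed into 80
#' families of 10 full sibs (800 offspring per generation, contribution cap
#' 4, no selfing), 13 generations with random selection through generation
#' 5, REML at generation 6, GBLUP truncation selection thereafter.
#'
#' @param ploidy even integer (2 or 4 for the shipped experiments).
#' @param trait a \linkS4class{TraitModel}.
#' @param genome list of founder-genome parameters (see
#'   \code{\link{simulateFounderGenome}}).
#' @param nParents,nFamilies,familySize,maxContrib,noSelfing crossing design.
#' @param nGenerations,randomUntil,remlAt scheme schedule.
#' @param selectionModel prediction model used for selection.
#' @param nEpistaticPairs epistatic pairs in the simulation model.
#' @param gainOn "u" or "g": scale on which the rate of gain is computed.
#' @return a \linkS4class{BreedingConfig}
#' @export
breedingConfig <- function(ploidy = 2L, trait = TraitModel(), genome = list(),
                           nParents = 80L, nFamilies = 80L, familySize = 10L,
                           maxContrib = 4L, noSelfing = TRUE,
                           nGenerations = 13L, randomUntil = 5L,
                           remlAt = 6L, selectionModel = "additive",
                           nEpistaticPairs = 0L, gainOn = "u") {
  new("BreedingConfig", ploidy = as.integer(ploidy), trait = trait,
      genome = genome, nParents = as.integer(nParents),
      nFamilies = as.integer(nFamilies), familySize = as.integer(familySize),
      maxContrib = as.integer(maxContrib), noSelfing = noSelfing,
      nGenerations = as.integer(nGenerations),
      randomUntil = as.integer(randomUntil), remlAt = as.integer(remlAt),
      selectionModel = selectionModel,
      nEpistaticPairs = as.integer(nEpistaticPairs), gainOn = gainOn)
}

allelismProfiles <- list(
  bi100      = data.frame(alleles = 2L, proportion = 1.0),
  bi80tri20  = data.frame(alleles = c(2L, 3L), proportion = c(0.8, 0.2)),
  bi50tri50  = data.frame(alleles = c(2L, 3L), proportion = c(0.5, 0.5)),
  bi80quad20 = data.frame(alleles = c(2L, 4L), proportion = c(0.8, 0.2)),
  bi50quad50 = data.frame(alleles = c(2L, 4L), proportion = c(0.5, 0.5)),
  bi20quad80 = data.frame(alleles = c(2L, 4L), proportion = c(0.2, 0.8)))

#' Reference experiment configurations
#'
#' Returns the configuration of the two shipped experiments: experiment 1
#' simulates additive effects only and compares multi-allelism levels and
#' ploidies; experiment 2 simulates additive, dominance and epistatic
#' effects (functional variances 1, 0.25, 0.25, 0.25, 0.25, residual 2) and
#' compares prediction models. \code{scale = "paper"} uses the full marker
#' and QTL panels (2k QTL, 10k markers from 50k/10k candidate pools);
#' \code{scale = "desk"} reduces the panels (1k QTL, 2.5k markers from
#' smaller candidate pools) while keeping the breeding design (80 parents,
#' 80 families of 10), genome length, historical-population parameters and
#' all trait parameters identical.
#'
#' @param example 1 or 2.
#' @param ploidy 2 or 4.
#' @param allelism one of "bi100", "bi80tri20", "bi50tri50", "bi80quad20",
#'   "bi50quad50", "bi20quad80".
#' @param selectionModel prediction model for selection (experiment 2).
#' @param scale "paper" or "desk".
#' @return a \linkS4class{BreedingConfig}
#' @export
exampleConfig <- function(example = 1L, ploidy = 2L, allelism = "bi100",
                          selectionModel = "additive",
                          scale = c("paper", "desk")) {
  scale <- match.arg(scale)
  profile <- allelismProfiles[[allelism]]
  if (is.null(profile)) stop("unknown allelism profile: ", allelism)
  maxA <- max(profile$alleles)
  desk <- scale == "desk"
  qtlPool <- if (!desk) 10000L else c(`2` = 4000L, `3` = 8000L,
                                      `4` = 13000L)[[as.character(maxA)]]
  genome <- list(chromLengths = rep(888.6 / 12, 12),
                 markerPool = if (desk) 8000L else 50000L,
                 qtlPool = qtlPool, qtlAlleles = maxA,
                 Ne = 200L, nGenerations = 1000L,
                 bottleneck = list(from = 901L, to = 950L, Ne = 100L),
                 mutationRate = 2.5e-3, nFounders = 100L,
                 nQtl = 2000L,
                 nMarkers = if (desk) 5000L else 10000L,
                 mafMin = 0.05, allelismProfile = profile)
  trait <- if (example == 1L) TraitModel(varA = 1, varE = 2)
           else TraitModel(varA = 1, varD = 0.25, varAA = 0.25,
                           varAD = 0.25, varDD = 0.25, varE = 2)
  breedingConfig(ploidy = ploidy, trait = trait, genome = genome,
                 selectionModel = selectionModel,
                 nEpistaticPairs = if (example == 1L) 0L
                                   else genome$nQtl %/% 2L,
                 gainOn = if (example == 1L) "u" else "g")
}

#' Replicate an experiment over founder populations and scheme runs
#'
#' Nested replication: each founder-population replicate draws its own
#' genome, founders, panel and effect set; each scheme replicate reruns the
#' breeding scheme (crossing, environmental noise, selection) from those
#' founders. Per-replicate seeds derive from the master seed, so results are
#' reproducible given (config, seed).
#'
#' @param config a \linkS4class{BreedingConfig}.
#' @param nFounderReps,nSchemeReps replication counts.
#' @param seed master seed.
#' @return list(replicates, summary, trajectories): per-replicate accuracy
#'   and gain, their mean/SD summary, and the Trajectory objects.
#' @export
replicateExperiment <- function(config, nFounderReps = 5L, nSchemeReps = 1L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fseeds <- sample.int(.Machine$integer.max, nFounderReps)
  rows <- list(); trajs <- list()
  for (i in seq_len(nFounderReps)) {
    set.seed(fseeds[i])
    fg <- simulateFounderGenome(config)
    effects <- generateEffects(fg$founders, fg$panel, config@trait,
                               nep = config@nEpistaticPairs)
    sseeds <- sample.int(.Machine$integer.max, nSchemeReps)
    for (j in seq_len(nSchemeReps)) {
      tr <- runBreedingScheme(config, fg$founders, fg$panel, effects,
                              seed = sseeds[j])
      rows[[length(rows) + 1L]] <- data.frame(founderRep = i, schemeRep = j,
                                              accuracy = tr@accuracy,
                                              gain = tr@gain)
      trajs[[length(trajs) + 1L]] <- tr
    }
  }
  reps <- do.call(rbind, rows)
  summ <- data.frame(metric = c("accuracy", "gain"),
                     mean = c(mean(reps$accuracy), mean(reps$gain)),
                     sd = c(stats::sd(reps$accuracy), stats::sd(reps$gain)))
  list(replicates = reps, summary = summ, trajectories = trajs)
}
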