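#' Simulate a historical population by Fisher-Wright reproduction
#'
#' Starts from equal per-allele frequencies at every locus (alleles assigned
#' in equal counts, randomly permuted across gene copies, so generation 0 is
#' at linkage equilibrium) and evolves the population by discrete-generation
#' random mating with recombination under bivalent chromosome pairing.
#' Drift can only lose alleles unless a historical K-allele mutation rate is
#' supplied; with \code{mutationRate = 0} allele counts per locus shrink
#' monotonically over time.
#'
#' @param map a \linkS4class{GeneticMap}; per-locus allele counts come from
#'   its loci table.
#' @param Ne effective (census) population size during ordinary generations.
#' @param nGenerations number of generations of random mating.
#' @param ploidy even integer.
#' @param bottleneck NULL or list(from, to, Ne): generation range (1-based,
#'   inclusive) with reduced population size.
#' @param mutationRate per-copy, per-generation probability that an allele
#'   copy is replaced by a uniformly drawn allele of the locus (historical
#'   phase only; default 0).
#' @return a \linkS4class{GenomePopulation} holding the final generation.
#' @export
simulateHistoricalPopulation <- function(map, Ne, nGenerations, ploidy = 2L,
                                         bottleneck = NULL, mutationRate = 0) {
  ploidy <- as.integer(ploidy)
  if (ploidy < 2L || ploidy %% 2L != 0L) stop("ploidy must be even and >= 2")
  if (Ne < 2) stop("Ne must be >= 2")
  if (nGenerations < 0) stop("nGenerations must be >= 0")
  sched <- rep(as.integer(Ne), nGenerations)
  if (!is.null(bottleneck)) {
    if (bottleneck$Ne < 2) stop("bottleneck Ne must be >= 2")
    w <- seq_len(nGenerations) >= bottleneck$from &
         seq_len(nGenerations) <= bottleneck$to
    sched[w] <- as.integer(bottleneck$Ne)
  }
  nl <- nrow(map@loci)
  if (nl == 0) stop("map has no loci")
  nA <- map@loci$nAlleles
  ncopies <- as.integer(Ne) * ploidy
  H <- matrix(raw(1), nl, ncopies)
  for (j in seq_len(nl)) {
    base <- rep_len(seq_len(nA[j]) - 1L, ncopies)
    H[j, ] <- as.raw(sample(base))
  }
  if (nGenerations > 0) {
    mi <- mapIndex(map)
    H <- cpp_historical(H, ploidy, sched, mutationRate, nA,
                        mi$chrStart, mi$chrEnd, mi$posM, mi$chrLenM)
  }
  GenomePopulation(map, ploidy, H)
}

#' Draw founders from a historical population
#'
#' Founders are fresh offspring of one round of random mating (without
#' selfing) among the final historical generation.
#'
#' @param pop a \linkS4class{GenomePopulation} (final historical generation).
#' @param nFounders number of founder individuals.
#' @return a \linkS4class{GenomePopulation} labeled generation 0.
#' @export
sampleFounders <- function(pop, nFounders) {
  n <- nInd(pop)
  if (n < 2) stop("need at least 2 historical individuals")
  mother <- sample.int(n, nFounders, replace = TRUE)
  father <- vapply(mother, function(m) {
    f <- sample.int(n, 1L)
    while (f == m) f <- sample.int(n, 1L)
    f
  }, integer(1))
  mi <- mapIndex(pop@map)
  H <- cpp_offspring(pop@haplotypes, pop@ploidy, mother - 1L, father - 1L,
                     mi$chrStart, mi$chrEnd, mi$posM, mi$chrLenM)
  GenomePopulation(pop@map, pop@ploidy, H)
}

#' One meiosis: a gamete from a parent
#'
#' Homologs pair two-by-two into randomly drawn bivalents per chromosome;
#' each bivalent contributes one recombinant chromatid, with the crossover
#' count Poisson in the chromosome length in Morgans and positions uniform
#' (Haldane mapping, no interference). Double reduction cannot occur.
#'
#' @param pop a \linkS4class{GenomePopulation}.
#' @param ind individual index (1-based).
#' @return raw matrix nLoci x (ploidy/2): the gamete's homologs.
#' @export
meiosis <- function(pop, ind) {
  if (nrow(pop@map@loci) == 0) stop("empty chromosome: map has no loci")
  mi <- mapIndex(pop@map)
  cpp_gamete(pop@haplotypes, pop@ploidy, as.integer(ind) - 1L,
             mi$chrStart, mi$chrEnd, mi$posM, mi$chrLenM)
}

#' Select QTL and marker panels under allelism and MAF constraints
#'
#' Markers are drawn from loci carrying exactly two alleles, both at
#' frequency >= \code{mafMin} in the reference population. QTL are drawn per
#' allelism class: a QTL assigned class c has exactly c alleles at frequency
#' >= \code{mafMin}. Class counts follow \code{allelismProfile} proportions
#' up to rounding.
#'
#' @param pop reference \linkS4class{GenomePopulation} (typically founders).
#' @param nQtl,nMarkers panel sizes.
#' @param mafMin per-allele frequency threshold for segregation (default
#'   0.05).
#' @param allelismProfile data.frame with columns \code{alleles} and
#'   \code{proportion} (proportions sum to 1).
#' @param qtlCandidates,markerCandidates integer map-locus indices of the
#'   candidate pools; default: loci whose map \code{pool} tag is "qtl"
#'   ("marker"), or all loci when no tags are present.
#' @return a \linkS4class{LociPanel}
#' @export
selectLoci <- function(pop, nQtl, nMarkers, mafMin = 0.05,
                       allelismProfile = data.frame(alleles = 2,
                                                    proportion = 1),
                       qtlCandidates = NULL, markerCandidates = NULL) {
  map <- pop@map
  pools <- map@loci$pool
  if (is.null(qtlCandidates))
    qtlCandidates <- if (any(pools == "qtl")) which(pools == "qtl")
                     else seq_len(nrow(map@loci))
  if (is.null(markerCandidates))
    markerCandidates <- if (any(pools == "marker")) which(pools == "marker")
                        else seq_len(nrow(map@loci))
  nAmax <- max(map@loci$nAlleles)
  freq <- alleleFrequencies(pop, nAlleles = nAmax)
  nSeg <- colSums(freq >= mafMin)
  nPresent <- colSums(freq > 0)

  ok <- markerCandidates[nPresent[markerCandidates] == 2L &
                         nSeg[markerCandidates] == 2L]
  if (length(ok) < nMarkers)
    stop(sprintf(paste0("insufficient marker loci: %d bi-allelic candidates ",
                        "with MAF >= %g, %d required"),
                 length(ok), mafMin, nMarkers))
  markers <- sort(sample(ok, nMarkers))

  prop <- allelismProfile$proportion
  if (abs(sum(prop) - 1) > 1e-8) stop("allelism proportions must sum to 1")
  counts <- diff(c(0L, round(cumsum(prop) * nQtl)))
  qtl <- integer(0); qtlAlleles <- integer(0)
  for (i in seq_along(counts)) {
    cls <- allelismProfile$alleles[i]
    elig <- setdiff(qtlCandidates[nSeg[qtlCandidates] == cls], markers)
    if (length(elig) < counts[i])
      stop(sprintf(paste0("insufficient QTL loci with %d segregating ",
                          "alleles: %d eligible, %d required"),
                   cls, length(elig), counts[i]))
    pick <- sample(elig, counts[i])
    qtl <- c(qtl, pick)
    qtlAlleles <- c(qtlAlleles, rep(as.integer(cls), counts[i]))
  }
  ord <- order(qtl)
  new("LociPanel", qtl = as.integer(qtl[ord]), qtlAlleles = qtlAlleles[ord],
      markers = as.integer(markers), alleleFreq = freq, mafMin = mafMin)
}

#' @describeIn selectLoci number of QTL in a panel
#' @param panel a LociPanel
#' @export
nQtl <- function(panel) length(panel@qtl)

#' @describeIn selectLoci maximum defined allele count of the panel's QTL on
#'   a given map (the allele dimension of effect matrices)
#' @param map the GeneticMap the panel refers to
#' @export
panelAlleleDim <- function(panel, map) max(map@loci$nAlleles[panel@qtl])

#' @export
setMethod("show", "LociPanel", function(object) {
  cat("LociPanel:", length(object@qtl), "QTL (",
      paste(sprintf("%d-allelic: %d", sort(unique(object@qtlAlleles)),
                    tabulate(object@qtlAlleles)[sort(unique(object@qtlAlleles))]),
            collapse = ", "), "),",
      length(object@markers), "bi-allelic markers, MAF >=",
      object@mafMin, "\n")
})
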