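#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' GeneticMap: chromosomes and locus coordinates
#'
#' Holds the chromosome structure (identifier and genetic length in
#' centimorgan) and the locus table (chromosome, position in cM, number of
#' defined alleles, and a candidate-pool tag used when drawing QTL and marker
#' panels). Loci are kept sorted by (chromosome, position).
#'
#' @slot chromosomes data.frame with columns \code{chrom} (integer id) and
#'   \code{lengthcM} (numeric genetic length).
#' @slot loci data.frame with columns \code{chrom}, \code{poscM},
#'   \code{nAlleles} and \code{pool} (character, e.g. "marker" or "qtl").
#' @export
setClass("GeneticMap",
  representation(chromosomes = "data.frame", loci = "data.frame"))

setValidity("GeneticMap", function(object) {
  ch <- object@chromosomes; lo <- object@loci
  msg <- character()
  if (!all(c("chrom", "lengthcM") %in% names(ch)))
    msg <- c(msg, "chromosomes needs columns chrom, lengthcM")
  if (!all(c("chrom", "poscM", "nAlleles", "pool") %in% names(lo)))
    msg <- c(msg, "loci needs columns chrom, poscM, nAlleles, pool")
  if (length(msg)) return(msg)
  if (anyDuplicated(ch$chrom)) msg <- c(msg, "duplicated chromosome ids")
  if (any(ch$lengthcM < 0)) msg <- c(msg, "negative chromosome length")
  if (!all(lo$chrom %in% ch$chrom)) msg <- c(msg, "locus on unknown chromosome")
  len <- ch$lengthcM[match(lo$chrom, ch$chrom)]
  if (any(lo$poscM < 0 | lo$poscM > len))
    msg <- c(msg, "locus position outside [0, chromosome length]")
  ord <- order(match(lo$chrom, ch$chrom), lo$poscM)
  if (!identical(ord, seq_len(nrow(lo))))
    msg <- c(msg, "loci must be sorted by (chromosome, position)")
  if (any(lo$nAlleles < 2)) msg <- c(msg, "loci need at least 2 alleles")
  if (length(msg)) msg else TRUE
})

#' GenomePopulation: haplotypes, pedigree and generation labels
#'
#' A set of individuals of common even ploidy. Haplotypes are a raw matrix of
#' dimension nLoci x (nInd * ploidy); the homologs of individual i occupy the
#' i-th block of \code{ploidy} columns. Allele codes are 0-based and bounded
#' by the per-locus allele count of the map.
#'
#' @slot map a \linkS4class{GeneticMap}.
#' @slot ploidy even integer >= 2.
#' @slot haplotypes raw matrix, nLoci x (nInd * ploidy).
#' @slot id integer individual identifiers (unique).
#' @slot mother,father integer ids of parents (NA for founders); parents
#'   precede offspring in id order.
#' @slot generation integer generation label per individual.
#' @export
setClass("GenomePopulation",
  representation(map = "GeneticMap", ploidy = "integer", haplotypes = "matrix",
                 id = "integer", mother = "integer", father = "integer",
                 generation = "integer"))

setValidity("GenomePopulation", function(object) {
  msg <- character()
  k <- object@ploidy
  if (length(k) != 1L || k < 2L || k %% 2L != 0L)
    msg <- c(msg, "ploidy must be a single even integer >= 2")
  n <- length(object@id)
  H <- object@haplotypes
  if (!is.raw(H[1L])) msg <- c(msg, "haplotypes must be a raw matrix")
  if (nrow(H) != nrow(object@map@loci)) msg <- c(msg, "haplotype rows != loci")
  if (length(msg)) return(msg)
  if (ncol(H) != n * k)
    msg <- c(msg, "haplotype columns != nInd * ploidy")
  if (anyDuplicated(object@id)) msg <- c(msg, "duplicated individual ids")
  for (s in c("mother", "father", "generation"))
    if (length(slot(object, s)) != n) msg <- c(msg, paste(s, "length != nInd"))
  if (length(msg)) return(msg)
  # parents must precede offspring whenever they are carried in this object
  # (parent ids may also refer to individuals kept elsewhere)
  for (s in c("mother", "father")) {
    pos <- match(slot(object, s), object@id)
    here <- !is.na(pos)
    if (any(pos[here] >= which(here)))
      msg <- c(msg, "parents must precede offspring")
  }
  # allele codes bounded by per-locus allele count
  if (n > 0) {
    mx <- cpp_row_max(H)
    if (any(mx >= object@map@loci$nAlleles))
      msg <- c(msg, "allele index exceeds locus allele count")
  }
  if (length(msg)) msg else TRUE
})

#' LociPanel: QTL and marker panels with allele-frequency context
#'
#' The split of map loci into a QTL panel (with per-locus segregating allele
#' counts) and a bi-allelic marker panel, plus per-allele frequencies in the
#' reference population the panel was drawn from.
#'
#' @slot qtl integer map-locus indices of the QTL.
#' @slot qtlAlleles integer number of segregating alleles (frequency >= mafMin)
#'   per QTL.
#' @slot markers integer map-locus indices of the bi-allelic markers.
#' @slot alleleFreq numeric matrix (max alleles x nLoci of the map) of allele
#'   frequencies in the reference population.
#' @slot mafMin numeric minor-allele-frequency threshold used.
#' @export
setClass("LociPanel",
  representation(qtl = "integer", qtlAlleles = "integer", markers = "integer",
                 alleleFreq = "matrix", mafMin = "numeric"))

setValidity("LociPanel", function(object) {
  msg <- character()
  if (length(intersect(object@qtl, object@markers)))
    msg <- c(msg, "QTL and marker sets must be disjoint")
  if (length(object@qtlAlleles) != length(object@qtl))
    msg <- c(msg, "qtlAlleles length != number of QTL")
  f <- object@alleleFreq
  cs <- colSums(f)
  if (length(cs) && any(abs(cs - 1) > 1e-8))
    msg <- c(msg, "allele frequencies per locus must sum to 1")
  if (length(msg)) msg else TRUE
})

#' TraitModel: functional variances and dominance-degree distribution
#'
#' Functional (biological) variance targets for each genotypic component in
#' the founder population, the environmental variance, and the normal
#' distribution of dominance degrees used to derive dominance effects from
#' additive ones.
#'
#' @slot varA,varD,varAA,varAD,varDD functional variances (trait units^2) of
#'   the additive, dominance, additive x additive, additive-dominance and
#'   dominance x dominance components.
#' @slot varE environmental variance.
#' @slot domMean,domVar mean and variance of the dominance degree
#'   distribution (defaults 0.19 and 0.097).
#' @slot rescaleMethod "by_individual" (default, captures LD covariance) or
#'   "by_locus".
#' @export
setClass("TraitModel",
  representation(varA = "numeric", varD = "numeric", varAA = "numeric",
                 varAD = "numeric", varDD = "numeric", varE = "numeric",
                 domMean = "numeric", domVar = "numeric",
                 rescaleMethod = "character"))

setValidity("TraitModel", function(object) {
  v <- c(object@varA, object@varD, object@varAA, object@varAD, object@varDD,
         object@varE, object@domVar)
  msg <- character()
  if (any(!is.finite(v)) || any(v < 0)) msg <- c(msg, "variances must be >= 0")
  if (!object@rescaleMethod %in% c("by_individual", "by_locus"))
    msg <- c(msg, "rescaleMethod must be by_individual or by_locus")
  if (length(msg)) msg else TRUE
})

#' EffectSet: functional allele and epistatic effects
#'
#' Additive and dominance allele effects (nB x nQtl), epistatic interaction
#' effects (nB^2 x nPairs) with their locus-pair map, and the population
#' intercept that re-centers founder total genetic values at zero.
#'
#' Epistatic effect vectors are stored with the allele index of the first
#' locus of the pair running fastest (Kronecker ordering of
#' covariates-of-locus-l (x) covariates-of-locus-k).
#'
#' @slot a,d numeric matrices nB x nQtl.
#' @slot aa,ad,da,dd numeric matrices nB^2 x nPairs.
#' @slot pairs integer matrix 2 x nPairs of QTL indices (positions within the
#'   panel's QTL vector); each QTL occurs in at most one pair.
#' @slot mu numeric founder mean of the raw genetic value.
#' @export
setClass("EffectSet",
  representation(a = "matrix", d = "matrix", aa = "matrix", ad = "matrix",
                 da = "matrix", dd = "matrix", pairs = "matrix",
                 mu = "numeric"))

setValidity("EffectSet", function(object) {
  msg <- character()
  nB <- nrow(object@a); nq <- ncol(object@a)
  if (!identical(dim(object@d), c(nB, nq))) msg <- c(msg, "dim(d) != dim(a)")
  np <- ncol(object@pairs)
  for (s in c("aa", "ad", "da", "dd")) {
    m <- slot(object, s)
    if (ncol(m) != np || nrow(m) != nB * nB)
      msg <- c(msg, sprintf("%s must be nB^2 x nPairs", s))
  }
  if (np > 0) {
    p <- as.vector(object@pairs)
    if (anyDuplicated(p)) msg <- c(msg, "each QTL in at most one pair")
    if (any(p < 1 | p > nq)) msg <- c(msg, "pair locus outside QTL panel")
  }
  if (length(msg)) msg else TRUE
})

#' GeneticValues: per-individual genotypic component totals
#'
#' @slot a,d,aa,ad,dd numeric component totals per individual (\code{ad} is
#'   the summed additive x dominance + dominance x additive component).
#' @slot g numeric total genetic value, centered by the founder mean mu.
#' @slot mu numeric the centering constant.
#' @export
setClass("GeneticValues",
  representation(a = "numeric", d = "numeric", aa = "numeric", ad = "numeric",
                 dd = "numeric", g = "numeric", mu = "numeric"))

#' GRMSet: genomic relationship matrices
#'
#' @slot Gu additive (VanRaden) matrix; \code{Gv} digenic dominance;
#'   \code{Guu}, \code{Guv}, \code{Gvv} Hadamard-product epistatic matrices.
#'   Unset components are NULL.
#' @export
setClass("GRMSet",
  representation(Gu = "matrixOrNULL", Gv = "matrixOrNULL",
                 Guu = "matrixOrNULL", Guv = "matrixOrNULL",
                 Gvv = "matrixOrNULL"))

#' MixedModelFit: GBLUP solutions and variance components
#'
#' @slot b named numeric fixed-effect solutions (generation means).
#' @slot random named list of numeric BLUP vectors (u, v, uu, uv, vv).
#' @slot varcomp named numeric variance components (one per random term plus
#'   \code{e}).
#' @slot converged logical (NA when the fit was not iterative).
#' @slot iterations integer count of REML iterations.
#' @slot logLik numeric restricted log-likelihood at the solution.
#' @slot trace data.frame iteration log (iteration, step type, logLik and the
#'   variance components).
#' @export
setClass("MixedModelFit",
  representation(b = "numeric", random = "list", varcomp = "numeric",
                 converged = "logical", iterations = "integer",
                 logLik = "numeric", trace = "data.frame"))

#' BreedingConfig: breeding-scheme and experiment parameters
#'
#' @slot ploidy even integer.
#' @slot trait a \linkS4class{TraitModel}.
#' @slot genome list describing founder-genome simulation: chromosome count
#'   and total length, candidate-pool sizes and allele counts, effective
#'   size and duration of the historical population, bottleneck schedule,
#'   historical mutation rate, founder count, panel sizes (nQtl, nMarkers),
#'   MAF threshold and the QTL allelism profile.
#' @slot nParents,nFamilies,familySize,maxContrib integers of the crossing
#'   design; \code{noSelfing} logical.
#' @slot nGenerations,randomUntil,remlAt integers: scheme length, last
#'   generation with random parent selection, generation at which variance
#'   components are estimated.
#' @slot selectionModel "additive", "additive_dominance" or
#'   "additive_dominance_epistasis".
#' @slot nEpistaticPairs integer epistatic pairs in the simulation model.
#' @slot gainOn "u" (additive value) or "g" (total genetic value).
#' @export
setClass("BreedingConfig",
  representation(ploidy = "integer", trait = "TraitModel", genome = "list",
                 nParents = "integer", nFamilies = "integer",
                 familySize = "integer", maxContrib = "integer",
                 noSelfing = "logical", nGenerations = "integer",
                 randomUntil = "integer", remlAt = "integer",
                 selectionModel = "character", nEpistaticPairs = "integer",
                 gainOn = "character"))

setValidity("BreedingConfig", function(object) {
  msg <- character()
  if (object@ploidy %% 2L != 0L) msg <- c(msg, "ploidy must be even")
  if (2L * object@nFamilies > object@maxContrib * object@nParents)
    msg <- c(msg, "infeasible: 2*nFamilies > maxContrib*nParents")
  if (!object@selectionModel %in%
      c("additive", "additive_dominance", "additive_dominance_epistasis"))
    msg <- c(msg, "unknown selectionModel")
  if (!object@gainOn %in% c("u", "g")) msg <- c(msg, "gainOn must be u or g")
  if (object@remlAt <= object@randomUntil)
    msg <- c(msg, "remlAt must exceed randomUntil")
  if (length(msg)) msg else TRUE
})

#' Trajectory: per-generation statistics of one scheme replicate
#'
#' @slot stats data.frame with one row per generation 0..nGenerations:
#'   mean/variance of the true additive value u and of the total genetic
#'   value g, and the phenotype mean.
#' @slot accuracy numeric Pearson correlation of true and predicted breeding
#'   values of the candidates at the REML generation.
#' @slot gain numeric rate of genetic gain, (mean at generation 13 - mean at
#'   generation 5) / 8 on the configured scale.
#' @slot details list: estimated variance components, REML convergence,
#'   selection model actually used, seeds.
#' @export
setClass("Trajectory",
  representation(stats = "data.frame", accuracy = "numeric", gain = "numeric",
                 details = "list"))
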