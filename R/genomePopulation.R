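#' Construct a GenomePopulation
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param ploidy even integer.
#' @param haplotypes raw matrix nLoci x (nInd * ploidy).
#' @param id integer ids (default 1..nInd).
#' @param mother,father integer parent ids (NA for founders).
#' @param generation integer generation labels.
#' @return a \linkS4class{GenomePopulation}
#' @export
GenomePopulation <- function(map, ploidy, haplotypes, id = NULL, mother = NULL,
                             father = NULL, generation = NULL) {
  n <- ncol(haplotypes) %/% ploidy
  if (is.null(id)) id <- seq_len(n)
  if (is.null(mother)) mother <- rep(NA_integer_, n)
  if (is.null(father)) father <- rep(NA_integer_, n)
  if (is.null(generation)) generation <- rep(0L, n)
  new("GenomePopulation", map = map, ploidy = as.integer(ploidy),
      haplotypes = haplotypes, id = as.integer(id),
      mother = as.integer(mother), father = as.integer(father),
      generation = as.integer(generation))
}

#' @rdname GenomePopulation
#' @param x,object a GenomePopulation
#' @export
nInd <- function(x) length(x@id)

#' @rdname GenomePopulation
#' @export
setGeneric("ploidy", function(x) standardGeneric("ploidy"))

#' @rdname GenomePopulation
#' @export
setMethod("ploidy", "GenomePopulation", function(x) x@ploidy)

#' @rdname GenomePopulation
#' @export
geneticMap <- function(x) x@map

#' @rdname GenomePopulation
#' @export
generations <- function(x) x@generation

#' @export
setMethod("show", "GenomePopulation", function(object) {
  cat("GenomePopulation:", nInd(object), "individuals, ploidy",
      object@ploidy, ",", nrow(object@haplotypes), "loci, generations",
      paste(range(object@generation), collapse = "-"), "\n")
})

#' @export
setMethod("[", "GenomePopulation", function(x, i, j, ..., drop = FALSE) {
  i <- seq_len(nInd(x))[i]
  cols <- as.vector(vapply(i, function(ii)
    ((ii - 1L) * x@ploidy + 1L):(ii * x@ploidy), integer(x@ploidy)))
  new("GenomePopulation", map = x@map, ploidy = x@ploidy,
      haplotypes = x@haplotypes[, cols, drop = FALSE], id = x@id[i],
      mother = x@mother[i], father = x@father[i],
      generation = x@generation[i])
})

#' Raw per-allele dosages
#'
#' Counts of each allele carried by each individual at the requested loci.
#' Dosages at a locus always sum to the ploidy.
#'
#' @param pop a \linkS4class{GenomePopulation}.
#' @param loci integer map-locus indices (1-based).
#' @param nAlleles number of allele slots in the result (default: maximum
#'   defined allele count among the requested loci).
#' @return integer array nInd x nLoci x nAlleles.
#' @export
dosageMatrix <- function(pop, loci, nAlleles = NULL) {
  nl <- nrow(pop@map@loci)
  if (any(loci < 1L | loci > nl)) stop("unknown locus index")
  if (is.null(nAlleles)) nAlleles <- max(pop@map@loci$nAlleles[loci])
  d <- cpp_dosage_all(pop@haplotypes, pop@ploidy, as.integer(loci) - 1L,
                      as.integer(nAlleles))
  arr <- array(d, dim = c(nInd(pop), nAlleles, length(loci)))
  aperm(arr, c(1L, 3L, 2L))
}

#' Dosage of a single counted allele per locus
#'
#' @inheritParams dosageMatrix
#' @param allele 1-based allele index to count (default 2, the conventional
#'   counted allele of a bi-allelic marker).
#' @return integer matrix nInd x nLoci.
#' @export
markerDosage <- function(pop, loci, allele = 2L) {
  nl <- nrow(pop@map@loci)
  if (any(loci < 1L | loci > nl)) stop("unknown locus index")
  cpp_dosage_allele(pop@haplotypes, pop@ploidy, as.integer(loci) - 1L,
                    as.integer(allele) - 1L)
}

#' Allele frequencies in a population
#'
#' @inheritParams dosageMatrix
#' @return numeric matrix nAlleles x nLoci of frequencies (columns sum to 1).
#' @export
alleleFrequencies <- function(pop, loci = seq_len(nrow(pop@map@loci)),
                              nAlleles = max(pop@map@loci$nAlleles)) {
  cpp_allele_freq(pop@haplotypes, pop@ploidy, as.integer(loci) - 1L,
                  as.integer(nAlleles))
}
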