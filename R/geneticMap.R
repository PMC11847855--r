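#' Construct a genetic map
#'
#' @param chromLengths numeric vector of chromosome lengths in centimorgan;
#'   chromosome ids are 1..length(chromLengths).
#' @param loci data.frame with columns \code{chrom}, \code{poscM},
#'   \code{nAlleles} and optionally \code{pool} (defaults to "locus"); rows
#'   are reordered to (chromosome, position).
#' @return a \linkS4class{GeneticMap}
#' @export
GeneticMap <- function(chromLengths, loci) {
  ch <- data.frame(chrom = seq_along(chromLengths),
                   lengthcM = as.numeric(chromLengths))
  if (is.null(loci$pool)) loci$pool <- "locus"
  loci$chrom <- as.integer(loci$chrom)
  loci$nAlleles <- as.integer(loci$nAlleles)
  loci <- loci[order(match(loci$chrom, ch$chrom), loci$poscM), , drop = FALSE]
  rownames(loci) <- NULL
  new("GeneticMap", chromosomes = ch, loci = loci)
}

#' Sample a genetic map with uniformly placed candidate loci
#'
#' Candidate loci are placed uniformly at random along the genome. Pools are
#' placed independently so that, for example, a bi-allelic marker pool and a
#' multi-allelic QTL pool can coexist on one map.
#'
#' @param chromLengths numeric chromosome lengths (cM).
#' @param pools data.frame with columns \code{pool} (name), \code{n} (locus
#'   count) and \code{nAlleles}.
#' @return a \linkS4class{GeneticMap}
#' @export
sampleGeneticMap <- function(chromLengths, pools) {
  tot <- sum(chromLengths)
  res <- do.call(rbind, lapply(seq_len(nrow(pools)), function(i) {
    n <- pools$n[i]
    gpos <- sort(stats::runif(n, 0, tot))
    cum <- cumsum(chromLengths)
    chrom <- findInterval(gpos, cum, left.open = TRUE) + 1L
    pos <- gpos - c(0, cum)[chrom]
    data.frame(chrom = chrom, poscM = pos, nAlleles = pools$nAlleles[i],
               pool = pools$pool[i])
  }))
  GeneticMap(chromLengths, res)
}

#' @describeIn GeneticMap number of loci
#' @param x,object a GeneticMap
#' @export
nLoci <- function(x) nrow(x@loci)

#' @export
setMethod("show", "GeneticMap", function(object) {
  cat("GeneticMap:", nrow(object@chromosomes), "chromosomes,",
      sum(object@chromosomes$lengthcM), "cM,", nrow(object@loci), "loci\n")
  print(table(object@loci$pool, object@loci$nAlleles))
})

# chromosome-wise locus index ranges and positions in Morgans, 0-based for C++
mapIndex <- function(map) {
  lo <- map@loci
  ids <- map@chromosomes$chrom
  start <- integer(length(ids)); end <- integer(length(ids))
  for (i in seq_along(ids)) {
    w <- which(lo$chrom == ids[i])
    start[i] <- if (length(w)) min(w) - 1L else 0L
    end[i] <- if (length(w)) max(w) else 0L
  }
  list(chrStart = start, chrEnd = end, posM = lo$poscM / 100,
       chrLenM = map@chromosomes$lengthcM / 100)
}
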