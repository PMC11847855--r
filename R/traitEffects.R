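#' Scaled additive covariate
#'
#' Maps a raw allele dosage t (0..ploidy) to the scaled additive covariate
#' (t - ploidy/2) * (2/ploidy), which runs from -1 (allele absent) to +1
#' (allele fixed in the genotype) and is antisymmetric under t -> ploidy - t.
#'
#' @param t raw dosage (vector ok).
#' @param ploidy even integer.
#' @return numeric covariate(s) in [-1, 1].
#' @export
additiveCovariate <- function(t, ploidy) {
  if (any(t < 0 | t > ploidy)) stop("dosage outside [0, ploidy]")
  (t - ploidy / 2) * (2 / ploidy)
}

#' Scaled dominance covariate
#'
#' Maps a raw dosage t to t * (ploidy - t) * (2/ploidy)^2, which is 0 for
#' fully homozygous dosages (t = 0 or ploidy), 1 at the balanced dosage
#' t = ploidy/2, and symmetric under t -> ploidy - t.
#'
#' @inheritParams additiveCovariate
#' @return numeric covariate(s) in [0, 1].
#' @export
dominanceCovariate <- function(t, ploidy) {
  if (any(t < 0 | t > ploidy)) stop("dosage outside [0, ploidy]")
  t * (ploidy - t) * (2 / ploidy)^2
}

#' Locus-level additive and dominance genotypic values
#'
#' The additive value is the covariate-weighted sum of allele effects,
#' a = sum_i t^a_i a_i, and the dominance value d = sum_i t^d_i d_i (digenic
#' dominance: each allele carries one dominance effect shared across
#' partners).
#'
#' @param t per-allele raw dosage vector (sums to ploidy), or a matrix
#'   individuals x alleles.
#' @param aCol,dCol per-allele effect vectors.
#' @param ploidy even integer.
#' @return named vector c(a, d), or a 2-column matrix for matrix input.
#' @export
locusValues <- function(t, aCol, dCol, ploidy) {
  if (is.matrix(t)) {
    if (ncol(t) != length(aCol) || ncol(t) != length(dCol))
      stop("effect vector length must match allele count")
    if (any(rowSums(t) != ploidy)) stop("dosages must sum to ploidy")
    return(cbind(a = additiveCovariate(t, ploidy) %*% aCol,
                 d = dominanceCovariate(t, ploidy) %*% dCol)[, 1:2])
  }
  if (length(t) != length(aCol) || length(t) != length(dCol))
    stop("effect vector length must match allele count")
  if (sum(t) != ploidy) stop("dosages must sum to ploidy")
  c(a = sum(additiveCovariate(t, ploidy) * aCol),
    d = sum(dominanceCovariate(t, ploidy) * dCol))
}

#' Two-locus epistatic genotypic values
#'
#' For a designated pair of loci (k, l), the additive x additive value is
#' (t^a_l Kronecker t^a_k) . aa, the additive-dominance value is the sum of
#' the additive x dominance and dominance x additive terms, and the
#' dominance x dominance value is (t^d_l Kronecker t^d_k) . dd. Effect
#' vectors have nB^2 elements with the locus-k allele index running fastest.
#'
#' @param tK,tL per-allele dosage vectors (or matrices individuals x alleles)
#'   at loci k and l.
#' @param aaCol,adCol,daCol,ddCol effect vectors of length nB^2.
#' @param ploidy even integer.
#' @return named vector c(aa, ad, dd) where ad is the combined
#'   additive-dominance value, or a 3-column matrix for matrix input.
#' @export
epistaticPairValues <- function(tK, tL, aaCol, adCol, daCol, ddCol, ploidy) {
  vec <- !is.matrix(tK)
  if (vec) { tK <- rbind(tK); tL <- rbind(tL) }
  nB <- ncol(tK)
  for (v in list(aaCol, adCol, daCol, ddCol))
    if (length(v) != nB * nB) stop("epistatic effect vectors must be nB^2")
  taK <- additiveCovariate(tK, ploidy); tdK <- dominanceCovariate(tK, ploidy)
  taL <- additiveCovariate(tL, ploidy); tdL <- dominanceCovariate(tL, ploidy)
  bil <- function(Xk, Xl, eff)  # rows: sum_{ik,il} Xk[,ik] Xl[,il] eff[(il-1)nB+ik]
    rowSums((Xk %*% matrix(eff, nB, nB)) * Xl)
  out <- cbind(aa = bil(taK, taL, aaCol),
               ad = bil(taK, tdL, adCol) + bil(tdK, taL, daCol),
               dd = bil(tdK, tdL, ddCol))
  if (vec) out[1L, ] else out
}

# covariate matrices n x (nB*nQtl) from a dosage array n x nQtl x nB,
# allele index fastest within each locus block (matches vec of nB x nQtl
# effect matrices)
covariateMatrices <- function(dos, ploidy) {
  n <- dim(dos)[1]; nq <- dim(dos)[2]; nB <- dim(dos)[3]
  ta <- aperm(additiveCovariate(dos, ploidy), c(1, 3, 2))
  td <- aperm(dominanceCovariate(dos, ploidy), c(1, 3, 2))
  dim(ta) <- c(n, nB * nq); dim(td) <- c(n, nB * nq)
  list(ta = ta, td = td, n = n, nq = nq, nB = nB)
}

# per-individual epistatic component totals given covariate matrices
epistaticTotals <- function(cv, effects) {
  np <- ncol(effects@pairs)
  n <- cv$n; nB <- cv$nB
  aaT <- adT <- ddT <- numeric(n)
  if (np == 0) return(list(aa = aaT, ad = adT, dd = ddT))
  for (p in seq_len(np)) {
    k <- effects@pairs[1, p]; l <- effects@pairs[2, p]
    ck <- ((k - 1) * nB + 1):(k * nB); cl <- ((l - 1) * nB + 1):(l * nB)
    taK <- cv$ta[, ck, drop = FALSE]; taL <- cv$ta[, cl, drop = FALSE]
    tdK <- cv$td[, ck, drop = FALSE]; tdL <- cv$td[, cl, drop = FALSE]
    aaT <- aaT + rowSums((taK %*% matrix(effects@aa[, p], nB, nB)) * taL)
    adT <- adT + rowSums((taK %*% matrix(effects@ad[, p], nB, nB)) * tdL) +
                 rowSums((tdK %*% matrix(effects@da[, p], nB, nB)) * taL)
    ddT <- ddT + rowSums((tdK %*% matrix(effects@dd[, p], nB, nB)) * tdL)
  }
  list(aa = aaT, ad = adT, dd = ddT)
}

#' Total genetic value of individuals
#'
#' Sums locus-level additive and dominance values over all QTL and epistatic
#' values over all designated pairs; the total is centered by the effect
#' set's founder mean mu.
#'
#' @param dosages integer array nInd x nQtl x nB of per-allele dosages
#'   covering every QTL of the effect set (see \code{\link{dosageMatrix}}).
#' @param effects an \linkS4class{EffectSet}.
#' @param ploidy even integer.
#' @return a \linkS4class{GeneticValues}
#' @export
totalGeneticValue <- function(dosages, effects, ploidy) {
  if (dim(dosages)[2] != ncol(effects@a) || dim(dosages)[3] != nrow(effects@a))
    stop("dosage array does not cover the effect set's QTL and alleles")
  cv <- covariateMatrices(dosages, ploidy)
  aT <- as.vector(cv$ta %*% as.vector(effects@a))
  dT <- as.vector(cv$td %*% as.vector(effects@d))
  ep <- epistaticTotals(cv, effects)
  raw <- aT + dT + ep$aa + ep$ad + ep$dd
  new("GeneticValues", a = aT, d = dT, aa = ep$aa, ad = ep$ad, dd = ep$dd,
      g = raw - effects@mu, mu = effects@mu)
}

#' Genetic values of a population at a panel's QTL
#'
#' @param pop a \linkS4class{GenomePopulation}.
#' @param panel a \linkS4class{LociPanel}.
#' @param effects an \linkS4class{EffectSet}.
#' @return a \linkS4class{GeneticValues}
#' @export
geneticValues <- function(pop, panel, effects) {
  dos <- dosageMatrix(pop, panel@qtl, nAlleles = nrow(effects@a))
  totalGeneticValue(dos, effects, pop@ploidy)
}

#' Construct a TraitModel
#'
#' @param varA,varD,varAA,varAD,varDD functional variances of the genotypic
#'   components in the founder population (defaults: additive 1, others 0).
#' @param varE environmental variance (default 2).
#' @param domMean,domVar dominance-degree distribution (defaults 0.19,
#'   0.097).
#' @param rescaleMethod "by_individual" or "by_locus".
#' @return a \linkS4class{TraitModel}
#' @export
TraitModel <- function(varA = 1, varD = 0, varAA = 0, varAD = 0, varDD = 0,
                       varE = 2, domMean = 0.19, domVar = 0.097,
                       rescaleMethod = "by_individual") {
  new("TraitModel", varA = varA, varD = varD, varAA = varAA, varAD = varAD,
      varDD = varDD, varE = varE, domMean = domMean, domVar = domVar,
      rescaleMethod = rescaleMethod)
}

# founder-frequency-weighted centering of additive allele effects:
# subtract sum_i p_i a_i per locus so the mean effect of a randomly drawn
# founder allele copy is zero at every QTL
centerAdditive <- function(a, freq) {
  sweep(a, 2, colSums(freq * a), "-")
}

# functional variance of a per-individual component total, by individual or
# as a sum of per-locus (per-pair) variances ignoring between-locus LD
componentVariance <- function(perLocus, method) {
  if (method == "by_individual") stats::var(rowSums(perLocus))
  else sum(apply(perLocus, 2, stats::var))
}

# per-locus additive or dominance values: n x nQtl matrix
perLocusFromCov <- function(covMat, eff, nB, nq) {
  n <- nrow(covMat)
  out <- matrix(0, n, nq)
  for (j in seq_len(nq))
    out[, j] <- covMat[, ((j - 1) * nB + 1):(j * nB), drop = FALSE] %*% eff[, j]
  out
}

perPairEpistatic <- function(cv, pairs, aa, ad, da, dd) {
  nB <- cv$nB; np <- ncol(pairs); n <- cv$n
  outAA <- matrix(0, n, max(np, 1)); outAD <- outAA; outDD <- outAA
  for (p in seq_len(np)) {
    k <- pairs[1, p]; l <- pairs[2, p]
    ck <- ((k - 1) * nB + 1):(k * nB); cl <- ((l - 1) * nB + 1):(l * nB)
    taK <- cv$ta[, ck, drop = FALSE]; taL <- cv$ta[, cl, drop = FALSE]
    tdK <- cv$td[, ck, drop = FALSE]; tdL <- cv$td[, cl, drop = FALSE]
    outAA[, p] <- rowSums((taK %*% matrix(aa[, p], nB, nB)) * taL)
    outAD[, p] <- rowSums((taK %*% matrix(ad[, p], nB, nB)) * tdL) +
                  rowSums((tdK %*% matrix(da[, p], nB, nB)) * taL)
    outDD[, p] <- rowSums((tdK %*% matrix(dd[, p], nB, nB)) * tdL)
  }
  list(aa = outAA, ad = outAD, dd = outDD)
}

#' Generate functional effects by sampling, centering and rescaling
#'
#' Additive allele effects are sampled from N(0, varA), centered per QTL so
#' the founder-frequency-weighted mean allele effect is zero, and rescaled
#' so the realized functional additive variance in the founders equals the
#' target. Dominance effects are dominance degrees (N(domMean, domVar))
#' times the absolute additive effect, rescaled to the dominance target.
#' Epistatic effects (aa, dd) are sampled and rescaled per component; the
#' additive-dominance effects ad and da are sampled independently and
#' rescaled jointly against the variance of their summed component. No
#' centering is applied to dominance or epistatic effects; the intercept mu
#' re-centers founder total genetic values at zero. Effects are fixed
#' thereafter (functional effects are frequency-independent).
#'
#' @param founders founder \linkS4class{GenomePopulation}.
#' @param panel a \linkS4class{LociPanel}.
#' @param trait a \linkS4class{TraitModel}.
#' @param nep number of epistatic pairs (each QTL in at most one pair; a
#'   random perfect matching when nep = nQtl/2).
#' @return an \linkS4class{EffectSet}
#' @export
generateEffects <- function(founders, panel, trait, nep = 0L) {
  k <- founders@ploidy
  nB <- panelAlleleDim(panel, founders@map)
  nq <- length(panel@qtl)
  dos <- dosageMatrix(founders, panel@qtl, nAlleles = nB)
  cv <- covariateMatrices(dos, k)
  freq <- panel@alleleFreq[seq_len(nB), panel@qtl, drop = FALSE]
  method <- trait@rescaleMethod
  rescale <- function(eff, perLocus, target, label) {
    prior <- componentVariance(perLocus, method)
    if (target == 0) return(eff * 0)
    if (!is.finite(prior) || prior < 1e-300)
      stop(sprintf("cannot rescale %s effects: zero realized prior variance",
                   label))
    eff * sqrt(target / prior)
  }

  a <- matrix(stats::rnorm(nB * nq, 0, sqrt(max(trait@varA, 1))), nB, nq)
  a <- centerAdditive(a, freq)
  a <- rescale(a, perLocusFromCov(cv$ta, a, nB, nq), trait@varA, "additive")

  delta <- matrix(stats::rnorm(nB * nq, trait@domMean, sqrt(trait@domVar)),
                  nB, nq)
  d <- delta * abs(a)
  d <- rescale(d, perLocusFromCov(cv$td, d, nB, nq), trait@varD, "dominance")

  if (nep > 0 && 2L * nep > nq) stop("nep exceeds nQtl/2")
  pairs <- if (nep > 0) matrix(sample.int(nq)[seq_len(2L * nep)], 2L, nep)
           else matrix(integer(0), 2L, 0L)
  sdAA <- sqrt(max(trait@varAA, 1)); sdAD <- sqrt(max(trait@varAD, 1))
  sdDD <- sqrt(max(trait@varDD, 1))
  aa <- matrix(stats::rnorm(nB * nB * nep, 0, sdAA), nB * nB, nep)
  ad <- matrix(stats::rnorm(nB * nB * nep, 0, sdAD), nB * nB, nep)
  da <- matrix(stats::rnorm(nB * nB * nep, 0, sdAD), nB * nB, nep)
  dd <- matrix(stats::rnorm(nB * nB * nep, 0, sdDD), nB * nB, nep)
  if (nep > 0) {
    pp <- perPairEpistatic(cv, pairs, aa, ad, da, dd)
    aa <- rescale(aa, pp$aa, trait@varAA, "additive x additive")
    dd <- rescale(dd, pp$dd, trait@varDD, "dominance x dominance")
    if (trait@varAD == 0) { ad <- ad * 0; da <- da * 0 }
    else {
      prior <- componentVariance(pp$ad, method)
      if (!is.finite(prior) || prior < 1e-300)
        stop("cannot rescale additive-dominance effects: zero prior variance")
      f <- sqrt(trait@varAD / prior)
      ad <- ad * f; da <- da * f
    }
  } else { aa <- aa * 0; ad <- ad * 0; da <- da * 0; dd <- dd * 0 }

  eff <- new("EffectSet", a = a, d = d, aa = aa, ad = ad, da = da, dd = dd,
             pairs = pairs, mu = 0)
  gv <- totalGeneticValue(dos, eff, k)
  eff@mu <- mean(gv@g)
  eff
}

#' Functional variance of a genotypic component in a reference population
#'
#' \code{by_individual} is the empirical variance of the component's
#' per-individual total; \code{by_locus} sums per-locus (or per-pair)
#' variances and therefore ignores covariance contributed by LD between
#' loci.
#'
#' @param effects an \linkS4class{EffectSet}.
#' @param pop reference \linkS4class{GenomePopulation}.
#' @param panel a \linkS4class{LociPanel}.
#' @param component one of "a", "d", "aa", "ad", "dd" (\code{ad} is the
#'   combined additive-dominance component).
#' @param method "by_individual" or "by_locus".
#' @return numeric variance
#' @export
functionalVariance <- function(effects, pop, panel,
                               component = c("a", "d", "aa", "ad", "dd"),
                               method = c("by_individual", "by_locus")) {
  component <- match.arg(component)
  method <- match.arg(method)
  nB <- nrow(effects@a)
  dos <- dosageMatrix(pop, panel@qtl, nAlleles = nB)
  cv <- covariateMatrices(dos, pop@ploidy)
  per <- switch(component,
    a = perLocusFromCov(cv$ta, effects@a, nB, cv$nq),
    d = perLocusFromCov(cv$td, effects@d, nB, cv$nq),
    {
      if (ncol(effects@pairs) == 0) return(0)
      pp <- perPairEpistatic(cv, effects@pairs, effects@aa, effects@ad,
                             effects@da, effects@dd)
      pp[[component]]
    })
  componentVariance(per, method)
}

#' Simulate phenotypes
#'
#' y = mu + g + e with independent environmental deviations e ~ N(0, varE).
#'
#' @param gv a \linkS4class{GeneticValues} or a numeric vector of genetic
#'   values.
#' @param mu population mean added to all phenotypes (default 0; founder
#'   genetic values are already centered at zero).
#' @param varE environmental variance (>= 0).
#' @return numeric phenotypes
#' @export
simulatePhenotypes <- function(gv, mu = 0, varE = 0) {
  if (varE < 0) stop("varE must be >= 0")
  g <- if (is(gv, "GeneticValues")) gv@g else gv
  mu + g + stats::rnorm(length(g), 0, sqrt(varE))
}

#' @export
setMethod("show", "EffectSet", function(object) {
  cat("EffectSet:", ncol(object@a), "QTL x", nrow(object@a), "alleles,",
      ncol(object@pairs), "epistatic pairs, mu =",
      signif(object@mu, 4), "\n")
})

#' @export
setMethod("show", "GeneticValues", function(object) {
  cat("GeneticValues for", length(object@g), "individuals: mean g =",
      signif(mean(object@g), 4), ", var g =", signif(stats::var(object@g), 4),
      "\n")
})
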