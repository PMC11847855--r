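#' Additive genomic relationship matrix (VanRaden, any even ploidy)
#'
#' Gu = W W' / (ploidy * sum_j p_j (1 - p_j)) with W the counted-allele
#' dosages centered by ploidy * p_j. Fixed markers (p in {0, 1}) are
#' excluded with a warning.
#'
#' @param M integer/numeric matrix individuals x markers of counted-allele
#'   dosages (0..ploidy).
#' @param ploidy even integer.
#' @param freq optional counted-allele frequencies; default colMeans(M) /
#'   ploidy (frequencies of the genotyped set itself).
#' @return symmetric matrix individuals x individuals
#' @export
additiveGRM <- function(M, ploidy, freq = NULL) {
  if (is.null(freq)) freq <- colMeans(M) / ploidy
  fixed <- freq <= 0 | freq >= 1
  if (any(fixed)) {
    warning(sum(fixed), " fixed marker(s) excluded from additive GRM")
    M <- M[, !fixed, drop = FALSE]; freq <- freq[!fixed]
  }
  if (!length(freq)) stop("no segregating markers")
  W <- sweep(M, 2, ploidy * freq, "-")
  tcrossprod(W) / (ploidy * sum(freq * (1 - freq)))
}

#' Digenic dominance genomic relationship matrix
#'
#' Diploids use the heterosis coding of Vitezica-type dominance models: for
#' counted-allele dosage t in {0, 1, 2} at frequency p the codes are -2p^2,
#' 2pq, -2q^2, and the denominator sum_j (2 p_j q_j)^2 gives a unit expected
#' diagonal under Hardy-Weinberg. Tetraploids use the digenic heterozygous
#' pair count h(t) = t (4 - t) centered by its HWE expectation 12 p q; the
#' normalizing constant is its HWE variance 36 p q - 120 p^2 q^2 per marker.
#' Both codings have zero mean under HWE. Degenerate markers are excluded.
#'
#' @inheritParams additiveGRM
#' @return symmetric matrix individuals x individuals
#' @export
dominanceGRM <- function(M, ploidy, freq = NULL) {
  if (!ploidy %in% c(2L, 4L))
    stop("dominance GRM supported for ploidy 2 and 4 only")
  if (is.null(freq)) freq <- colMeans(M) / ploidy
  # fixed markers and markers without dosage variation (e.g. a column of
  # identical heterozygotes) carry no dominance contrast
  constant <- colSums(abs(sweep(M, 2, M[1, ]))) == 0
  fixed <- freq <= 0 | freq >= 1 | constant
  if (any(fixed)) {
    warning(sum(fixed), " degenerate marker(s) excluded from dominance GRM")
    M <- M[, !fixed, drop = FALSE]; freq <- freq[!fixed]
  }
  if (!length(freq)) stop("no usable markers")
  n <- nrow(M); p <- freq; q <- 1 - freq
  if (ploidy == 2L) {
    P <- matrix(p, n, length(p), byrow = TRUE)
    D <- (M == 0) * (-2 * P^2) + (M == 1) * (2 * P * (1 - P)) +
         (M == 2) * (-2 * (1 - P)^2)
    denom <- sum((2 * p * q)^2)
  } else {
    H <- M * (4 - M)
    D <- sweep(H, 2, 12 * p * q, "-")
    denom <- sum(36 * p * q - 120 * p^2 * q^2)
  }
  tcrossprod(D) / denom
}

#' Epistatic relationship matrices by Hadamard products
#'
#' Guu = Gu o Gu, Guv = Gu o Gv, Gvv = Gv o Gv (elementwise).
#'
#' @param Gu,Gv additive and dominance relationship matrices (conformable).
#' @return a \linkS4class{GRMSet} with all five matrices.
#' @export
epistaticGRMs <- function(Gu, Gv) {
  if (!all(dim(Gu) == dim(Gv))) stop("Gu and Gv must be conformable")
  new("GRMSet", Gu = Gu, Gv = Gv, Guu = Gu * Gu, Guv = Gu * Gv,
      Gvv = Gv * Gv)
}

#' @export
setMethod("show", "GRMSet", function(object) {
  have <- Filter(function(s) !is.null(slot(object, s)),
                 c("Gu", "Gv", "Guu", "Guv", "Gvv"))
  n <- if (length(have)) nrow(slot(object, have[1])) else 0
  cat("GRMSet:", n, "individuals; components:", paste(have, collapse = ", "),
      "\n")
})
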