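#' Solve GBLUP mixed-model equations at known variances
#'
#' Fits y = Xb + sum_c Z u_c + e with u_c ~ N(0, G_c sigma_c^2) and
#' e ~ N(0, I sigmaE^2), where the fixed effects are generation means. The
#' solve goes through the phenotypic covariance V = sum_c sigma_c^2 G_c +
#' sigmaE^2 I, which is algebraically identical to Henderson's mixed-model
#' equations; BLUPs are returned for every individual carried by the
#' relationship matrices, including genotyped-but-unphenotyped candidates.
#'
#' @param y numeric phenotypes.
#' @param generation fixed-effect labels (one level per generation).
#' @param grms named list of relationship matrices (e.g. u, v, uu, uv, vv),
#'   all n x n over the same individuals.
#' @param varcomp named numeric variances matching \code{grms}.
#' @param varE residual variance.
#' @param phenotyped integer indices (rows of the G matrices) of the
#'   phenotyped individuals, aligned with \code{y}; default: all.
#' @return a \linkS4class{MixedModelFit}
#' @export
solveGBLUP <- function(y, generation, grms, varcomp, varE,
                       phenotyped = NULL) {
  y <- as.vector(y)
  nG <- nrow(grms[[1]])
  if (is.null(phenotyped)) phenotyped <- seq_len(nG)
  n <- length(y)
  stopifnot(length(phenotyped) == n, all(names(varcomp) %in% names(grms)) ||
              is.null(names(varcomp)))
  if (is.null(names(varcomp))) names(varcomp) <- names(grms)
  if (any(varcomp < 0) || varE < 0) stop("variances must be >= 0")
  X <- genDesign(generation)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design not full column rank")
  allPhen <- identical(phenotyped, seq_len(nG))
  V <- NULL
  for (cn in names(grms))
    if (varcomp[[cn]] > 0) {
      term <- varcomp[[cn]] * (if (allPhen) grms[[cn]]
                               else grms[[cn]][phenotyped, phenotyped])
      V <- if (is.null(V)) term else V + term
    }
  if (is.null(V)) V <- diag(varE, n) else diag(V) <- diag(V) + varE
  ch <- tryCatch(chol(V), error = function(e) {
    # ridge stabilization for (near-)singular V
    chol(V + diag(1e-6 * mean(diag(V)), n))
  })
  solveV <- function(z) backsolve(ch, backsolve(ch, z, transpose = TRUE))
  ViX <- solveV(X)
  Viy <- solveV(y)
  XtViX <- crossprod(X, ViX)
  b <- solve(XtViX, crossprod(X, Viy))
  r <- y - X %*% b
  w <- solveV(r)
  random <- lapply(names(grms), function(cn) {
    if (varcomp[[cn]] > 0)
      as.vector(varcomp[[cn]] *
                  (if (allPhen) grms[[cn]] %*% w
                   else grms[[cn]][, phenotyped] %*% w))
    else numeric(nG)
  })
  names(random) <- names(grms)
  yPy <- sum(y * w)  # y'Py = y'V^-1 (y - X bhat)
  logL <- -0.5 * (2 * sum(log(diag(ch))) +
                  determinant(XtViX, logarithm = TRUE)$modulus + yPy)
  bv <- as.vector(b); names(bv) <- colnames(X)
  new("MixedModelFit", b = bv, random = random,
      varcomp = c(unlist(varcomp), e = varE), converged = NA,
      iterations = 0L, logLik = as.numeric(logL),
      trace = data.frame())
}

# one-column-per-generation incidence design (cell-means coding, works for
# a single level too)
genDesign <- function(generation) {
  lev <- sort(unique(generation))
  X <- vapply(lev, function(l) as.numeric(generation == l),
              numeric(length(generation)))
  X <- matrix(X, nrow = length(generation))
  colnames(X) <- as.character(lev)
  X
}

# one REML evaluation (dense path): restricted logL, scores, AI matrix and
# the tr(PH)/y'PHPy pieces for components theta = (grm variances..., varE)
remlEvalDense <- function(theta, y, X, grms) {
  n <- length(y); C <- length(grms)
  V <- diag(theta[C + 1], n)
  for (i in seq_len(C)) V <- V + theta[i] * grms[[i]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  P <- Vi - ViX %*% solve(XtViX, t(ViX))
  py <- as.vector(P %*% y)
  logL <- -0.5 * (2 * sum(log(diag(ch))) +
                  determinant(XtViX, logarithm = TRUE)$modulus +
                  sum(y * py))
  q <- matrix(0, n, C + 1)
  trPH <- numeric(C + 1)
  for (i in seq_len(C)) {
    q[, i] <- grms[[i]] %*% py
    trPH[i] <- sum(P * grms[[i]])
  }
  q[, C + 1] <- py
  trPH[C + 1] <- sum(diag(P))
  yPHPy <- as.vector(crossprod(py, q))
  AI <- 0.5 * crossprod(q, P %*% q)
  list(logL = as.numeric(logL), trPH = trPH, yPHPy = yPHPy, AI = AI)
}

# one REML evaluation (single-GRM path, rotated to the eigenbasis of G so
# every iteration is O(n p^2))
remlEvalRotated <- function(theta, yt, Xt, lam) {
  v <- theta[1] * lam + theta[2]
  if (any(v <= 0)) return(NULL)
  A <- crossprod(Xt, Xt / v)
  chA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(chA)) return(NULL)
  solveA <- function(z) backsolve(chA, backsolve(chA, z, transpose = TRUE))
  b <- solveA(crossprod(Xt, yt / v))
  py <- as.vector((yt - Xt %*% b) / v)
  logL <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(chA))) + sum(yt * py))
  Pz <- function(z) z / v -
    as.vector(Xt %*% solveA(crossprod(Xt, z / v))) / v
  trPH <- c(sum(lam / v) - sum(diag(solve(A, crossprod(Xt, Xt * (lam / v^2))))),
            sum(1 / v) - sum(diag(solve(A, crossprod(Xt, Xt / v^2)))))
  q1 <- lam * py; q2 <- py
  yPHPy <- c(sum(py * q1), sum(py * q2))
  P1 <- Pz(q1); P2 <- Pz(q2)
  AI <- 0.5 * matrix(c(sum(q1 * P1), sum(q1 * P2),
                       sum(q1 * P2), sum(q2 * P2)), 2, 2)
  list(logL = as.numeric(logL), trPH = trPH, yPHPy = yPHPy, AI = AI)
}

#' REML variance components by average information with EM fallback
#'
#' Estimates one variance per relationship matrix plus a residual variance
#' by maximizing the restricted likelihood. Updates use the
#' average-information (AI) algorithm; whenever an AI step fails (singular
#' or negative-definite AI matrix, non-finite or decreasing likelihood) an
#' expectation-maximization step with step halving is substituted, which
#' keeps the likelihood non-decreasing. Variances are clamped at a small
#' positive floor and flagged as boundary estimates. With a single
#' relationship matrix the problem is rotated to its eigenbasis once, after
#' which every iteration costs O(n) matrix-free work.
#'
#' @inheritParams solveGBLUP
#' @param init optional named starting variances (grm components and e);
#'   default: equal split of var(y).
#' @param maxIter maximum iterations (default 200).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @return a \linkS4class{MixedModelFit} carrying estimates, convergence
#'   flag, iteration trace, and BLUP solutions at the estimates.
#' @export
remlEstimate <- function(y, generation, grms, init = NULL, maxIter = 200L,
                         tol = 1e-8) {
  y <- as.vector(y)
  C <- length(grms)
  n <- length(y)
  if (n < C + 1 + length(unique(generation)))
    stop("more parameters than records")
  X <- genDesign(generation)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design not full column rank")
  vy <- stats::var(y)
  floorV <- 1e-8 * vy
  theta <- if (is.null(init)) rep(vy / (C + 1), C + 1)
           else pmax(as.numeric(init), floorV)
  rotated <- (C == 1L)
  if (rotated) {
    ev <- eigen(grms[[1]], symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    yt <- as.vector(crossprod(ev$vectors, y))
    Xt <- crossprod(ev$vectors, X)
    evalF <- function(th) remlEvalRotated(th, yt, Xt, lam)
  } else {
    evalF <- function(th) remlEvalDense(th, y, X, grms)
  }
  cur <- evalF(theta)
  if (is.null(cur)) stop("REML evaluation failed at starting values")
  tr <- data.frame(iteration = 0L, step = "init", logLik = cur$logL)
  converged <- FALSE
  it <- 0L
  emStep <- function(th, ev) pmax(th + th^2 * (ev$yPHPy - ev$trPH) / n, floorV)
  while (it < maxIter) {
    it <- it + 1L
    step <- "ai"
    newTheta <- NULL
    if (it > 1L) { # first iteration always EM to stabilize
      # score_c = -0.5 (tr(PH_c) - y'PH_cPy)
      score <- -0.5 * (cur$trPH - cur$yPHPy)
      delta <- tryCatch(solve(cur$AI, score), error = function(e) NULL)
      if (!is.null(delta) && all(is.finite(delta)))
        newTheta <- pmax(theta + delta, floorV)
    }
    nxt <- if (!is.null(newTheta)) evalF(newTheta) else NULL
    if (is.null(nxt) || !is.finite(nxt$logL) || nxt$logL < cur$logL - 1e-8) {
      step <- "em"
      newTheta <- emStep(theta, cur)
      nxt <- evalF(newTheta)
      h <- 0L
      while ((is.null(nxt) || !is.finite(nxt$logL) ||
              nxt$logL < cur$logL - 1e-10) && h < 20L) {
        h <- h + 1L
        newTheta <- (newTheta + theta) / 2
        nxt <- evalF(newTheta)
      }
      if (is.null(nxt) || !is.finite(nxt$logL)) break
    }
    dL <- nxt$logL - cur$logL
    theta <- newTheta; cur <- nxt
    tr <- rbind(tr, data.frame(iteration = it, step = step,
                               logLik = cur$logL))
    if (abs(dL) < tol * (1 + abs(cur$logL))) { converged <- TRUE; break }
  }
  names(theta) <- c(names(grms), "e")
  # flag components that collapsed toward the lower boundary
  boundary <- theta <= 1e-3 * vy
  tr$boundary <- paste(names(theta)[boundary], collapse = ",")
  fit <- solveGBLUP(y, generation, grms, theta[seq_len(C)], theta[C + 1])
  new("MixedModelFit", b = fit@b, random = fit@random, varcomp = theta,
      converged = converged, iterations = it, logLik = cur$logL, trace = tr)
}

#' @export
setMethod("show", "MixedModelFit", function(object) {
  cat("MixedModelFit:", length(object@b), "fixed effects,",
      length(object@random), "random term(s)\n  variances:",
      paste(sprintf("%s=%.4g", names(object@varcomp), object@varcomp),
            collapse = ", "), "\n  converged:", object@converged,
      "(", object@iterations, "iterations )\n")
})
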