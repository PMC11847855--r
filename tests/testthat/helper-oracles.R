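# Independent brute-force evaluators used as oracles. These deliberately use
# plain loops and re-derive every covariate from the raw dosage definition,
# so they share no code path with the package implementation.

oracle_ta <- function(t, k) (t - k / 2) * (2 / k)
oracle_td <- function(t, k) t * (k - t) * (2 / k)^2

# component totals for every individual by exhaustive summation
oracle_total <- function(dos, effects, k) {
  n <- dim(dos)[1]; nq <- dim(dos)[2]; nB <- dim(dos)[3]
  out <- matrix(0, n, 5, dimnames = list(NULL, c("a", "d", "aa", "ad", "dd")))
  np <- ncol(effects@pairs)
  for (i in seq_len(n)) {
    for (j in seq_len(nq)) for (b in seq_len(nB)) {
      out[i, "a"] <- out[i, "a"] + oracle_ta(dos[i, j, b], k) * effects@a[b, j]
      out[i, "d"] <- out[i, "d"] + oracle_td(dos[i, j, b], k) * effects@d[b, j]
    }
    if (np) for (p in seq_len(np)) {
      kk <- effects@pairs[1, p]; ll <- effects@pairs[2, p]
      for (bk in seq_len(nB)) for (bl in seq_len(nB)) {
        idx <- (bl - 1) * nB + bk
        tak <- oracle_ta(dos[i, kk, bk], k); tdk <- oracle_td(dos[i, kk, bk], k)
        tal <- oracle_ta(dos[i, ll, bl], k); tdl <- oracle_td(dos[i, ll, bl], k)
        out[i, "aa"] <- out[i, "aa"] + tak * tal * effects@aa[idx, p]
        out[i, "ad"] <- out[i, "ad"] + tak * tdl * effects@ad[idx, p] +
                                       tdk * tal * effects@da[idx, p]
        out[i, "dd"] <- out[i, "dd"] + tdk * tdl * effects@dd[idx, p]
      }
    }
  }
  out
}

# random dosage array with rows summing to the ploidy
random_dosage <- function(n, nq, nB, k) {
  dos <- array(0L, c(n, nq, nB))
  for (i in seq_len(n)) for (j in seq_len(nq)) {
    al <- sample.int(nB, k, replace = TRUE)
    for (b in seq_len(nB)) dos[i, j, b] <- sum(al == b)
  }
  dos
}

# random effect set for nq QTL, nB alleles and np pairs
random_effects <- function(nq, nB, np) {
  new("EffectSet",
      a = matrix(rnorm(nB * nq), nB, nq),
      d = matrix(rnorm(nB * nq), nB, nq),
      aa = matrix(rnorm(nB * nB * np), nB * nB, np),
      ad = matrix(rnorm(nB * nB * np), nB * nB, np),
      da = matrix(rnorm(nB * nB * np), nB * nB, np),
      dd = matrix(rnorm(nB * nB * np), nB * nB, np),
      pairs = if (np) matrix(sample.int(nq)[seq_len(2 * np)], 2, np)
              else matrix(integer(0), 2, 0),
      mu = 0)
}

# a small random-mated founder population with segregating loci
small_founders <- function(nLociQtl = 400, nLociMarker = 400, ploidy = 2,
                           Ne = 100, gens = 200, nAllelesQtl = 2) {
  map <- sampleGeneticMap(c(60, 60),
    data.frame(pool = c("marker", "qtl"), n = c(nLociMarker, nLociQtl),
               nAlleles = c(2L, nAllelesQtl)))
  hp <- simulateHistoricalPopulation(map, Ne = Ne, nGenerations = gens,
                                     ploidy = ploidy, mutationRate = 2.5e-3)
  sampleFounders(hp, 100)
}
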