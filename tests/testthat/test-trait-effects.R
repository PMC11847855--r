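# Covariates, locus-level and epistatic genotypic values, effect generation.

test_that("additive and dominance covariates reproduce the bi-allelic conversion tables", {
  # diploid rows: genotype (t1, t2) -> (t1a, t2a, t1d, t2d)
  dip <- rbind(c(2, 0, 1, -1, 0, 0),
               c(1, 1, 0, 0, 1, 1),
               c(0, 2, -1, 1, 0, 0))
  tet <- rbind(c(4, 0, 1, -1, 0, 0),
               c(3, 1, 1 / 2, -1 / 2, 3 / 4, 3 / 4),
               c(2, 2, 0, 0, 1, 1),
               c(1, 3, -1 / 2, 1 / 2, 3 / 4, 3 / 4),
               c(0, 4, -1, 1, 0, 0))
  for (row in seq_len(nrow(dip))) {
    expect_identical(additiveCovariate(dip[row, 1:2], 2), dip[row, 3:4])
    expect_identical(dominanceCovariate(dip[row, 1:2], 2), dip[row, 5:6])
  }
  for (row in seq_len(nrow(tet))) {
    expect_identical(additiveCovariate(tet[row, 1:2], 4), tet[row, 3:4])
    expect_identical(dominanceCovariate(tet[row, 1:2], 4), tet[row, 5:6])
  }
})

test_that("covariates are antisymmetric (additive) and symmetric (dominance) with the stated ranges", {
  for (k in c(2, 4, 6, 8)) {
    t <- 0:k
    expect_equal(additiveCovariate(t, k), -additiveCovariate(k - t, k))
    expect_equal(dominanceCovariate(t, k), dominanceCovariate(k - t, k))
    expect_true(all(additiveCovariate(t, k) >= -1 &
                    additiveCovariate(t, k) <= 1))
    expect_true(all(dominanceCovariate(t, k) >= 0 &
                    dominanceCovariate(t, k) <= 1))
    expect_identical(additiveCovariate(0, k), -1)
    expect_identical(dominanceCovariate(k / 2, k), 1)
    expect_identical(dominanceCovariate(c(0, k), k), c(0, 0))
  }
  expect_error(additiveCovariate(3, 2), "outside")
  expect_error(dominanceCovariate(-1, 4), "outside")
})

test_that("bi-allelic locus values match the symbolic one-locus table and the substitution parameterization", {
  set.seed(1)
  for (rep in 1:5) {
    a1 <- rnorm(1); a2 <- rnorm(1); d1 <- rnorm(1); d2 <- rnorm(1)
    aCol <- c(a1, a2); dCol <- c(d1, d2)
    # diploid: -(a2 - a1), 0, +(a2 - a1); dominance 0, d1 + d2, 0
    expect_equal(locusValues(c(2, 0), aCol, dCol, 2),
                 c(a = -(a2 - a1), d = 0))
    expect_equal(locusValues(c(1, 1), aCol, dCol, 2),
                 c(a = 0, d = d1 + d2))
    expect_equal(locusValues(c(0, 2), aCol, dCol, 2),
                 c(a = a2 - a1, d = 0))
    # tetraploid rows, including the 1/2 and 3/4 entries
    expect_equal(locusValues(c(4, 0), aCol, dCol, 4),
                 c(a = -(a2 - a1), d = 0))
    expect_equal(locusValues(c(3, 1), aCol, dCol, 4),
                 c(a = -0.5 * (a2 - a1), d = 0.75 * (d1 + d2)))
    expect_equal(locusValues(c(2, 2), aCol, dCol, 4),
                 c(a = 0, d = d1 + d2))
    expect_equal(locusValues(c(1, 3), aCol, dCol, 4),
                 c(a = 0.5 * (a2 - a1), d = 0.75 * (d1 + d2)))
    expect_equal(locusValues(c(0, 4), aCol, dCol, 4),
                 c(a = a2 - a1, d = 0))
  }
  # worked numeric case: tetraploid dosage (3,1), d = (0.2, 0.6)
  expect_equal(locusValues(c(3, 1), c(0, 0), c(0.2, 0.6), 4)[["d"]], 0.6)
  # tri-allelic diploid: the non-carried allele still contributes via ta = -1
  expect_equal(locusValues(c(1, 1, 0), c(0.5, -0.5, 9.9), c(0, 0, 0), 2)[["a"]],
               -9.9)
  expect_error(locusValues(c(1, 1), c(1, 2, 3), c(0, 0), 2), "length")
  expect_error(locusValues(c(2, 1), c(1, 2), c(0, 0), 2), "sum to ploidy")
})

test_that("bi-allelic epistatic values match the two-locus table where it follows the equations", {
  set.seed(2)
  aa <- rnorm(4); ad <- rnorm(4); da <- rnorm(4); dd <- rnorm(4)
  ep <- function(tK, tL) epistaticPairValues(tK, tL, aa, ad, da, dd, 2)
  # double homozygote B1B1 x B1B1: +aa1 - aa2 - aa3 + aa4
  expect_equal(ep(c(2, 0), c(2, 0))[["aa"]], aa[1] - aa[2] - aa[3] + aa[4])
  # B2B2 x B2B2 (last row): +aa1 - aa2 - aa3 + aa4
  expect_equal(ep(c(0, 2), c(0, 2))[["aa"]], aa[1] - aa[2] - aa[3] + aa[4])
  # double heterozygote: dd1 + dd2 + dd3 + dd4, aa = 0
  v <- ep(c(1, 1), c(1, 1))
  expect_equal(v[["dd"]], sum(dd))
  expect_equal(v[["aa"]], 0)
  # heterozygous locus k kills every aa value regardless of locus l
  for (tL in list(c(2, 0), c(1, 1), c(0, 2)))
    expect_equal(ep(c(1, 1), tL)[["aa"]], 0)
  # additive-dominance rows that the equations force
  expect_equal(ep(c(2, 0), c(1, 1))[["ad"]], ad[1] - ad[2] + ad[3] - ad[4])
  expect_equal(ep(c(0, 2), c(1, 1))[["ad"]], -ad[1] + ad[2] - ad[3] + ad[4])
})

test_that("epistatic values agree with the exhaustive double-sum oracle", {
  set.seed(3)
  for (k in c(2, 4, 6)) for (nB in c(2, 3, 4)) {
    eff <- random_effects(2, nB, 1)
    dos <- random_dosage(6, 2, nB, k)
    got <- epistaticPairValues(dos[, 1, ], dos[, 2, ], eff@aa[, 1],
                               eff@ad[, 1], eff@da[, 1], eff@dd[, 1], k)
    eff@pairs <- matrix(c(1L, 2L), 2, 1)
    want <- oracle_total(dos, eff, k)
    expect_equal(unname(got[, "aa"]), unname(want[, "aa"]), tolerance = 1e-12)
    expect_equal(unname(got[, "ad"]), unname(want[, "ad"]), tolerance = 1e-12)
    expect_equal(unname(got[, "dd"]), unname(want[, "dd"]), tolerance = 1e-12)
  }
})

test_that("total genetic value equals the brute-force oracle and degenerates correctly", {
  set.seed(4)
  for (rep in 1:40) {
    k <- sample(c(2, 4, 6), 1)
    nB <- sample(2:4, 1)
    nq <- sample(2:5, 1)
    np <- sample(0:min(2, nq %/% 2), 1)
    eff <- random_effects(nq, nB, np)
    dos <- random_dosage(5, nq, nB, k)
    gv <- totalGeneticValue(dos, eff, k)
    want <- oracle_total(dos, eff, k)
    expect_equal(gv@g, unname(rowSums(want)), tolerance = 1e-12)
    expect_equal(gv@a, unname(want[, "a"]), tolerance = 1e-12)
    expect_equal(gv@ad, unname(want[, "ad"]), tolerance = 1e-12)
  }
  # all-zero effects give g identically zero
  eff0 <- random_effects(3, 2, 1)
  for (s in c("a", "d", "aa", "ad", "da", "dd"))
    slot(eff0, s) <- slot(eff0, s) * 0
  dos <- random_dosage(4, 3, 2, 2)
  expect_equal(totalGeneticValue(dos, eff0, 2)@g, rep(0, 4))
  # additive-only effects reduce to the plain sum of locus additive values
  effA <- random_effects(3, 2, 0)
  effA@d <- effA@d * 0
  gvA <- totalGeneticValue(dos, effA, 2)
  expect_equal(gvA@g, gvA@a)
  expect_equal(gvA@d + gvA@aa + gvA@ad + gvA@dd, rep(0, 4))
})

test_that("generated effects hit the functional variance targets with zero weighted locus means", {
  set.seed(5)
  fo <- small_founders(nLociQtl = 300, nLociMarker = 50)
  pan <- selectLoci(fo, nQtl = 100, nMarkers = 20)
  tr <- TraitModel(varA = 1, varD = 0.25, varAA = 0.25, varAD = 0.25,
                   varDD = 0.25, varE = 2)
  ef <- generateEffects(fo, pan, tr, nep = 50)
  expect_equal(functionalVariance(ef, fo, pan, "a"), 1, tolerance = 1e-6)
  for (cp in c("d", "aa", "ad", "dd"))
    expect_equal(functionalVariance(ef, fo, pan, cp), 0.25, tolerance = 1e-6)
  # founder-frequency-weighted mean allele effect is zero at every QTL
  freq <- pan@alleleFreq[seq_len(nrow(ef@a)), pan@qtl]
  expect_lt(max(abs(colSums(freq * ef@a))), 1e-10)
  # founder mean of g is zero after mu adjustment
  gv <- geneticValues(fo, pan, ef)
  expect_lt(abs(mean(gv@g)), 1e-10)
  # each QTL in at most one pair; here exactly one when nep = nqtl/2
  expect_identical(sort(as.vector(ef@pairs)), 1:100)
})

test_that("centering and rescaling are idempotent", {
  set.seed(6)
  fo <- small_founders(nLociQtl = 150, nLociMarker = 50)
  pan <- selectLoci(fo, nQtl = 60, nMarkers = 20)
  ef <- generateEffects(fo, pan, TraitModel(varA = 1, varE = 2), nep = 0)
  freq <- pan@alleleFreq[seq_len(nrow(ef@a)), pan@qtl]
  a2 <- polybreed:::centerAdditive(ef@a, freq)
  expect_equal(a2, ef@a, tolerance = 1e-12)
  v <- functionalVariance(ef, fo, pan, "a")
  expect_equal(ef@a * sqrt(1 / v), ef@a, tolerance = 1e-12)
})

test_that("zeroed variance components produce exactly zero effect matrices", {
  set.seed(7)
  fo <- small_founders(nLociQtl = 150, nLociMarker = 50)
  pan <- selectLoci(fo, nQtl = 60, nMarkers = 20)
  ef <- generateEffects(fo, pan, TraitModel(varA = 1, varE = 2), nep = 10)
  expect_true(all(ef@d == 0) && all(ef@aa == 0) && all(ef@ad == 0) &&
              all(ef@da == 0) && all(ef@dd == 0))
  expect_gt(functionalVariance(ef, fo, pan, "a"), 0.99)
})

test_that("a founder population without genetic variation cannot be rescaled", {
  map <- GeneticMap(50, data.frame(chrom = 1, poscM = c(10, 30),
                                   nAlleles = 2, pool = "qtl"))
  H <- matrix(as.raw(0), 2, 20)  # 10 diploid clones, all homozygous
  pop <- GenomePopulation(map, 2, H)
  pan <- new("LociPanel", qtl = c(1L, 2L), qtlAlleles = c(1L, 1L),
             markers = integer(0), alleleFreq = alleleFrequencies(pop),
             mafMin = 0.05)
  expect_error(generateEffects(pop, pan, TraitModel(varA = 1)),
               "zero realized prior variance")
})

test_that("dominance degrees follow the configured distribution", {
  set.seed(8)
  delta <- rnorm(2e4, 0.19, sqrt(0.097))
  expect_lt(abs(mean(delta) - 0.19), 0.01)
  # and the generator consumes that distribution: dominance prior is
  # delta * |a|, so with huge domMean the d component correlates with |a|
  fo <- small_founders(nLociQtl = 150, nLociMarker = 50)
  pan <- selectLoci(fo, nQtl = 60, nMarkers = 20)
  ef <- generateEffects(fo, pan, TraitModel(varA = 1, varD = 0.25, varE = 2,
                                            domMean = 5, domVar = 1e-4))
  expect_gt(cor(as.vector(abs(ef@a)), as.vector(ef@d)), 0.9)
})

test_that("functional variance methods agree and diverge as LD dictates", {
  # single-QTL panel: by_locus equals by_individual exactly
  set.seed(9)
  fo <- small_founders(nLociQtl = 100, nLociMarker = 50)
  pan1 <- selectLoci(fo, nQtl = 1, nMarkers = 5)
  ef1 <- generateEffects(fo, pan1, TraitModel(varA = 1, varE = 2))
  expect_equal(functionalVariance(ef1, fo, pan1, "a", "by_locus"),
               functionalVariance(ef1, fo, pan1, "a", "by_individual"),
               tolerance = 1e-12)
  # two loci in perfect positive LD with equal effects: individual > locus
  map <- GeneticMap(50, data.frame(chrom = 1, poscM = c(10, 30),
                                   nAlleles = 2, pool = "qtl"))
  # 10 diploids whose dosage varies across individuals but is identical at
  # the two loci (complete positive LD)
  H <- matrix(as.raw(0), 2, 20)
  geno <- rep(c(0, 1, 2), length.out = 10)
  for (i in 1:10) {
    hom1 <- if (geno[i] >= 1) c(1, 1) else c(0, 0)
    hom2 <- if (geno[i] == 2) c(1, 1) else c(0, 0)
    H[, (i - 1) * 2 + 1] <- as.raw(hom1)
    H[, (i - 1) * 2 + 2] <- as.raw(hom2)
  }
  pop <- GenomePopulation(map, 2, H)
  pan <- new("LociPanel", qtl = c(1L, 2L), qtlAlleles = c(2L, 2L),
             markers = integer(0), alleleFreq = alleleFrequencies(pop),
             mafMin = 0.05)
  ef <- new("EffectSet", a = matrix(c(0, 1, 0, 1), 2, 2),
            d = matrix(0, 2, 2), aa = matrix(0, 4, 0), ad = matrix(0, 4, 0),
            da = matrix(0, 4, 0), dd = matrix(0, 4, 0),
            pairs = matrix(integer(0), 2, 0), mu = 0)
  expect_gt(functionalVariance(ef, pop, pan, "a", "by_individual"),
            functionalVariance(ef, pop, pan, "a", "by_locus") * 1.5)
})

test_that("phenotypes add independent environmental noise of the requested variance", {
  set.seed(10)
  g <- rnorm(1e4)
  expect_identical(simulatePhenotypes(g, mu = 1.5, varE = 0), 1.5 + g)
  y <- simulatePhenotypes(g, varE = 2)
  expect_equal(var(y - g), 2, tolerance = 0.1)
  expect_error(simulatePhenotypes(g, varE = -1), ">= 0")
})
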