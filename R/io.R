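#' Load an experiment configuration from YAML
#'
#' The file names an experiment (1 or 2), ploidy, allelism profile,
#' selection model and scale, with optional \code{trait} and
#' \code{breeding} blocks overriding individual defaults. Unknown or
#' invalid fields fail with the field name.
#'
#' @param path YAML file.
#' @return a \linkS4class{BreedingConfig}
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  need <- function(x, field, default) if (is.null(x[[field]])) default
                                      else x[[field]]
  example <- need(cfg, "example", 1L)
  if (!example %in% c(1L, 2L)) stop("invalid field 'example': must be 1 or 2")
  ploidy <- need(cfg, "ploidy", 2L)
  if (ploidy %% 2 != 0) stop("invalid field 'ploidy': must be even")
  allelism <- need(cfg, "allelism", "bi100")
  if (!allelism %in% names(allelismProfiles))
    stop("invalid field 'allelism': ", allelism)
  scale <- need(cfg, "scale", "desk")
  model <- need(cfg, "selection_model", "additive")
  conf <- exampleConfig(example, ploidy, allelism, model, scale)
  if (!is.null(cfg$trait)) {
    tr <- cfg$trait
    known <- c("varA", "varD", "varAA", "varAD", "varDD", "varE",
               "domMean", "domVar", "rescaleMethod")
    bad <- setdiff(names(tr), known)
    if (length(bad)) stop("unknown trait field: ", bad[1])
    for (f in setdiff(known, "rescaleMethod")) {
      if (!is.null(tr[[f]])) {
        if (!is.numeric(tr[[f]]) || (f != "domMean" && tr[[f]] < 0))
          stop("invalid trait field '", f, "': must be a non-negative number")
        slot(conf@trait, f) <- as.numeric(tr[[f]])
      }
    }
    if (!is.null(tr$rescaleMethod)) conf@trait@rescaleMethod <- tr$rescaleMethod
    validObject(conf@trait)
  }
  if (!is.null(cfg$breeding)) {
    br <- cfg$breeding
    known <- c("nParents", "nFamilies", "familySize", "maxContrib",
               "noSelfing", "nGenerations", "randomUntil", "remlAt",
               "nEpistaticPairs")
    bad <- setdiff(names(br), known)
    if (length(bad)) stop("unknown breeding field: ", bad[1])
    for (f in known) if (!is.null(br[[f]])) {
      v <- br[[f]]
      slot(conf, f) <- if (is.logical(slot(conf, f))) as.logical(v)
                       else as.integer(v)
    }
    validObject(conf)
  }
  conf
}

#' Write an experiment configuration to YAML
#'
#' Inverse of \code{\link{loadConfig}} for the fields it reads; a loaded
#' configuration round-trips.
#'
#' @param config a \linkS4class{BreedingConfig}.
#' @param example,allelism,scale the constructor arguments to record.
#' @param path output YAML file.
#' @export
writeConfig <- function(config, path, example = 1L, allelism = "bi100",
                        scale = "desk") {
  tr <- config@trait
  yaml::write_yaml(list(
    example = as.integer(example), ploidy = as.integer(config@ploidy),
    allelism = allelism, scale = scale,
    selection_model = config@selectionModel,
    trait = list(varA = tr@varA, varD = tr@varD, varAA = tr@varAA,
                 varAD = tr@varAD, varDD = tr@varDD, varE = tr@varE,
                 domMean = tr@domMean, domVar = tr@domVar,
                 rescaleMethod = tr@rescaleMethod),
    breeding = list(nParents = config@nParents, nFamilies = config@nFamilies,
                    familySize = config@familySize,
                    maxContrib = config@maxContrib,
                    noSelfing = config@noSelfing,
                    nGenerations = config@nGenerations,
                    randomUntil = config@randomUntil, remlAt = config@remlAt,
                    nEpistaticPairs = config@nEpistaticPairs)), path)
  invisible(path)
}

# deterministic string fingerprint for manifests: polynomial rolling hash
# modulo a Mersenne prime, exact in double arithmetic
strHash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Deterministic in-memory fixtures
#'
#' Small populations, panels and effect sets for tests and examples.
#' \code{worked_tables} covers every bi-allelic genotype dosage class of the
#' diploid and tetraploid conversion tables at two interacting loci;
#' \code{tiny_diploid} and \code{tiny_tetraploid} are 10-individual,
#' 5-locus random populations.
#'
#' @param kind fixture name.
#' @param seed integer seed (fixtures are deterministic given the seed).
#' @param ploidy ploidy of the worked-tables fixture (2 or 4).
#' @return list(pop, panel, effects)
#' @export
makeFixture <- function(kind = c("tiny_diploid", "tiny_tetraploid",
                                 "worked_tables"), seed = 1L, ploidy = 2L) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "worked_tables") {
    k <- as.integer(ploidy)
    # two loci on one 100 cM chromosome; individuals enumerate all dosage
    # pairs (t_k, t_l) in 0..k
    map <- GeneticMap(100, data.frame(chrom = 1, poscM = c(20, 80),
                                      nAlleles = 2, pool = "qtl"))
    dose <- expand.grid(t1 = 0:k, t2 = 0:k)
    n <- nrow(dose)
    H <- matrix(raw(1), 2, n * k)
    for (i in seq_len(n)) {
      cols <- (i - 1) * k + seq_len(k)
      H[1, cols] <- as.raw(c(rep(0L, dose$t1[i]), rep(1L, k - dose$t1[i])))
      H[2, cols] <- as.raw(c(rep(0L, dose$t2[i]), rep(1L, k - dose$t2[i])))
    }
    pop <- GenomePopulation(map, k, H)
    freq <- alleleFrequencies(pop)
    panel <- new("LociPanel", qtl = c(1L, 2L), qtlAlleles = c(2L, 2L),
                 markers = integer(0), alleleFreq = freq, mafMin = 0.05)
    effects <- new("EffectSet",
                   a = matrix(c(0.3, -0.2, 0.1, 0.4), 2, 2),
                   d = matrix(c(0.05, 0.15, 0.2, 0.1), 2, 2),
                   aa = matrix(c(0.1, -0.2, 0.3, -0.4), 4, 1),
                   ad = matrix(c(0.2, 0.1, -0.1, 0.3), 4, 1),
                   da = matrix(c(-0.3, 0.2, 0.1, -0.2), 4, 1),
                   dd = matrix(c(0.15, 0.25, -0.05, 0.1), 4, 1),
                   pairs = matrix(c(1L, 2L), 2, 1), mu = 0)
    return(list(pop = pop, panel = panel, effects = effects))
  }
  k <- if (kind == "tiny_diploid") 2L else 4L
  map <- GeneticMap(c(60, 40),
                    data.frame(chrom = c(1, 1, 1, 2, 2),
                               poscM = c(5, 25, 50, 10, 30), nAlleles = 2,
                               pool = c("qtl", "qtl", "marker", "marker",
                                        "marker")))
  n <- 10L
  H <- matrix(as.raw(sample(0:1, 5 * n * k, replace = TRUE)), 5, n * k)
  pop <- GenomePopulation(map, k, H)
  freq <- alleleFrequencies(pop)
  panel <- new("LociPanel", qtl = c(1L, 2L), qtlAlleles = c(2L, 2L),
               markers = c(3L, 4L, 5L), alleleFreq = freq, mafMin = 0.05)
  effects <- new("EffectSet",
                 a = matrix(stats::rnorm(4), 2, 2),
                 d = matrix(stats::rnorm(4, 0, 0.3), 2, 2),
                 aa = matrix(0, 4, 0), ad = matrix(0, 4, 0),
                 da = matrix(0, 4, 0), dd = matrix(0, 4, 0),
                 pairs = matrix(integer(0), 2, 0), mu = 0)
  list(pop = pop, panel = panel, effects = effects)
}

#' Write experiment outputs
#'
#' Writes one per-generation trajectory CSV per replicate, a replicate
#' summary CSV (mean and SD of accuracy and gain), and a JSON run manifest
#' holding the master seed, configuration fingerprint and output paths.
#'
#' @param result list as returned by \code{\link{replicateExperiment}}.
#' @param dir output directory (created if needed).
#' @param config the \linkS4class{BreedingConfig} used (recorded in the
#'   manifest).
#' @param seed master seed used (recorded in the manifest).
#' @return invisible manifest list
#' @export
writeOutputs <- function(result, dir, config = NULL, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(result$trajectories)) {
    p <- file.path(dir, sprintf("trajectory_%03d.csv", i))
    utils::write.csv(result$trajectories[[i]]@stats, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  reps <- result$replicates
  if (is.null(reps))
    reps <- data.frame(founderRep = integer(0), schemeRep = integer(0),
                       accuracy = numeric(0), gain = numeric(0))
  repPath <- file.path(dir, "replicates.csv")
  utils::write.csv(reps, repPath, row.names = FALSE)
  summ <- result$summary
  if (is.null(summ))
    summ <- data.frame(metric = character(0), mean = numeric(0),
                       sd = numeric(0))
  sumPath <- file.path(dir, "summary.csv")
  utils::write.csv(summ, sumPath, row.names = FALSE)
  cfgStr <- if (is.null(config)) "" else
    paste(deparse(list(ploidy = config@ploidy, model = config@selectionModel,
                       genome = config@genome)), collapse = "")
  manifest <- list(version = as.character(utils::packageVersion("polybreed")),
                   seed = seed, configHash = strHash(cfgStr),
                   trajectories = paths, replicates = repPath,
                   summary = sumPath)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Export marker genotypes as multi-allelic VCF
#'
#' Optional export through the vcfR package; genotypes are written as
#' unphased allele-index calls (e.g. "0/0/1/1" for a tetraploid). Allele
#' letters are synthetic placeholders.
#'
#' @param pop a \linkS4class{GenomePopulation}.
#' @param loci map-locus indices to export (default: all).
#' @param file output path (".vcf.gz" is appended by vcfR).
#' @export
exportVCF <- function(pop, loci = seq_len(nrow(pop@map@loci)), file) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("exportVCF requires the vcfR package")
  k <- pop@ploidy
  lo <- pop@map@loci[loci, , drop = FALSE]
  letters4 <- c("A", "C", "G", "T")
  fix <- cbind(CHROM = as.character(lo$chrom),
               POS = as.character(round(lo$poscM * 1e4)),
               ID = paste0("locus", loci), REF = "A",
               ALT = vapply(lo$nAlleles,
                            function(a) paste(letters4[2:a], collapse = ","),
                            character(1)),
               QUAL = ".", FILTER = "PASS", INFO = ".")
  n <- nInd(pop)
  H <- pop@haplotypes[loci, , drop = FALSE]
  gt <- matrix("", length(loci), n)
  for (i in seq_len(n)) {
    cols <- (i - 1) * k + seq_len(k)
    block <- matrix(as.integer(H[, cols]), nrow = length(loci))
    gt[, i] <- apply(block, 1, function(z) paste(sort(z), collapse = "/"))
  }
  colnames(gt) <- paste0("ind", pop@id)
  gt <- cbind(FORMAT = "GT", gt)
  v <- new("vcfR", meta = c("##fileformat=VCFv4.3",
                            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
           fix = fix, gt = gt)
  vcfR::write.vcf(v, file)
  invisible(file)
}
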