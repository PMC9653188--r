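# Shared builders for the test suite. Everything is generated in code; no
# binary fixtures.

# A small, fast population: 3 stations on 3 short chromosomes with a dense
# map, so that all LD distance classes below 100 Mb are populated.
smallPopConfig <- function(seed = 1, nAccessions = 240, nMarkers = 300,
                           nStations = 3, ...) {
  simConfig("barley", nAccessions = nAccessions, nMarkers = nMarkers,
            nStations = nStations,
            chromSizes = data.frame(chrom = c("c1", "c2", "c3"),
                                    size_mb = c(120, 100, 80)),
            unplacedRefMb = 0, seed = seed, ...)
}

# Trait list with no station/year shifts, for clean heritability checks.
plainTrait <- function(h2, nQtl = 50, name = "T") {
  list(list(name = name, nQtl = nQtl, h2 = h2, stationEffectSd = 0,
            yearEffectSd = 0, scaleSdLog = 0))
}

# Phenotype vector aligned to the genotype columns of `gd`.
alignedY <- function(gd, pheno, trait = "T", col = "value") {
  sub <- pheno[pheno$trait == trait, ]
  sub[[col]][match(colnames(dosages(gd)), sub$accession)]
}

# Best label agreement between a clustering and true labels over all
# permutations (small k only).
permAgreement <- function(cluster, truth) {
  cluster <- as.integer(factor(cluster))
  truth <- as.integer(factor(truth))
  k <- max(cluster, truth)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(seq_len(k)))
    best <- max(best, mean(p[cluster] == truth))
  best
}

# Minimal GenotypeData from a dosage matrix (sites x accessions).
makeGD <- function(d, chrom = "c1", pos = NULL) {
  d <- as.matrix(d)
  if (is.null(pos)) pos <- seq_len(nrow(d)) * 1000000L
  GenotypeData(d, data.frame(marker_id = sprintf("m%03d", seq_len(nrow(d))),
                             chrom = rep_len(chrom, nrow(d)),
                             pos_bp = as.integer(pos)))
}

# Random candidate catalog on given chromosome sizes, positions uniform.
randomCatalog <- function(n, chromSizes, seed = 1) {
  set.seed(seed)
  nPer <- pmax(2L, round(n * chromSizes$size_mb / sum(chromSizes$size_mb)))
  rows <- lapply(seq_len(nrow(chromSizes)), function(i) {
    data.frame(chrom = chromSizes$chrom[i],
               pos_bp = sort(as.integer(
                 runif(nPer[i], 1, chromSizes$size_mb[i] * 1e6))))
  })
  cat <- do.call(rbind, rows)
  data.frame(marker_id = sprintf("C%05d", seq_len(nrow(cat))), cat,
             missing_rate = rbeta(nrow(cat), 1.5, 8),
             maf = 0.5 * rbeta(nrow(cat), 2, 1.2),
             map_class = sample(1:5, nrow(cat), replace = TRUE,
                                prob = c(.45, .25, .15, .10, .05)),
             n_extra_polymorphisms = rpois(nrow(cat), 0.24))
}
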