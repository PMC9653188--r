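# Reference chromosome names/sizes (Mb) used by the presets: the seven
# barley chromosomes (IBSC v2 scale, plus unplaced length) and the 21
# wheat chromosomes (IWGSC RefSeq v1.0 scale).
.barleyChromSizes <- data.frame(
  chrom = c("1H", "2H", "3H", "4H", "5H", "6H", "7H"),
  size_mb = c(558.5, 768.1, 699.7, 647.1, 670.0, 583.4, 657.2))
.barleyUnplacedMb <- 249.8
.wheatChromSizes <- data.frame(
  chrom = c("1A", "2A", "3A", "4A", "5A", "6A", "7A",
            "1B", "2B", "3B", "4B", "5B", "6B", "7B",
            "1D", "2D", "3D", "4D", "5D", "6D", "7D"),
  size_mb = c(594.1, 780.8, 750.8, 744.6, 709.8, 618.1, 736.7,
              689.9, 801.3, 830.8, 673.6, 713.1, 721.0, 750.6,
              495.5, 651.9, 615.6, 509.9, 566.1, 473.6, 638.7))
.wheatUnplacedMb <- 481.0

#' Configuration for the breeding-population simulator
#'
#' Defines a synthetic breeding program: a marker map over the preset
#' chromosomes, station-structured subpopulations diverged by a
#' Balding-Nichols drift parameter, accessions derived from biparental
#' crosses among a small set of inbred founders per station followed by
#' repeated selfing (Haldane recombination, no interference), and polygenic
#' traits with station-by-year location and scale shifts.
#'
#' The presets mirror the two platforms the package targets: `"barley"`
#' gives 1,032 accessions x 768 markers on 7 chromosomes from 8 stations,
#' `"wheat"` 1,798 x 960 on 21 chromosomes. Any field can be overridden.
#'
#' @param preset `"barley"` or `"wheat"`.
#' @param nAccessions,nMarkers,nStations population dimensions.
#' @param chromSizes data.frame `chrom`, `size_mb`.
#' @param unplacedRefMb unplaced reference length (enters coverage totals
#'   only).
#' @param fst Balding-Nichols divergence between station subpopulations
#'   (default 0.1, enough to separate stations on the leading principal
#'   components).
#' @param founderCount inbred founders per station (default 6; few
#'   founders create realistic long-range LD within stations).
#' @param selfingGenerations generations of selfing after the cross
#'   (default 6, residual heterozygosity about 2^-6).
#' @param recombRateCmPerMb genetic map density (default 0.25 cM/Mb, a
#'   genome-wide average for large-genome temperate cereals).
#' @param ldScaleMb decay length (Mb) of the latent haplotype correlation
#'   used when drawing founder haplotypes (default 5, concentrating
#'   linkage disequilibrium below about 5 Mb as in advanced breeding
#'   material); 0 draws sites independently.
#' @param missingRate genotype missing-call injection rate (default 0.02).
#' @param jitter marker-position jitter as a fraction of the mean spacing
#'   (0 = exactly uniform; default 0.4).
#' @param years harvest years (default 2018:2019).
#' @param traits list of trait specifications, each a list with `name`,
#'   `nQtl`, `h2`, `stationEffectSd`, `yearEffectSd`, `scaleSdLog`.
#'   Defaults: a high-heritability thousand-grain-weight-like trait
#'   (h2 = 0.7), an intermediate heading-date-like trait (h2 = 0.5) and a
#'   low-heritability protein-like trait (h2 = 0.3).
#' @param seed single integer driving every random draw.
#' @return A list of class `"SimConfig"`.
#' @export
simConfig <- function(preset = c("barley", "wheat"),
                      nAccessions = NULL, nMarkers = NULL, nStations = 8,
                      chromSizes = NULL, unplacedRefMb = NULL,
                      fst = 0.1, founderCount = 6, selfingGenerations = 6,
                      recombRateCmPerMb = 0.25, ldScaleMb = 5,
                      missingRate = 0.02, jitter = 0.4,
                      years = c(2018, 2019), traits = NULL, seed = 1) {
  preset <- match.arg(preset)
  if (preset == "barley") {
    if (is.null(chromSizes)) chromSizes <- .barleyChromSizes
    if (is.null(unplacedRefMb)) unplacedRefMb <- .barleyUnplacedMb
    if (is.null(nMarkers)) nMarkers <- 768L
    if (is.null(nAccessions)) nAccessions <- 1032L
  } else {
    if (is.null(chromSizes)) chromSizes <- .wheatChromSizes
    if (is.null(unplacedRefMb)) unplacedRefMb <- .wheatUnplacedMb
    if (is.null(nMarkers)) nMarkers <- 960L
    if (is.null(nAccessions)) nAccessions <- 1798L
  }
  if (is.null(traits))
    traits <- list(
      list(name = "TGW", nQtl = 60, h2 = 0.7, stationEffectSd = 1,
           yearEffectSd = 0.5, scaleSdLog = 0.15),
      list(name = "DH", nQtl = 40, h2 = 0.5, stationEffectSd = 1.5,
           yearEffectSd = 0.5, scaleSdLog = 0.15),
      list(name = "GPC", nQtl = 30, h2 = 0.3, stationEffectSd = 1,
           yearEffectSd = 0.5, scaleSdLog = 0.15))
  cfg <- list(preset = preset, nAccessions = as.integer(nAccessions),
              nMarkers = as.integer(nMarkers),
              nStations = as.integer(nStations), chromSizes = chromSizes,
              unplacedRefMb = unplacedRefMb, fst = fst,
              founderCount = as.integer(founderCount),
              selfingGenerations = as.integer(selfingGenerations),
              recombRateCmPerMb = recombRateCmPerMb, ldScaleMb = ldScaleMb,
              missingRate = missingRate, jitter = jitter, years = years,
              traits = traits, seed = as.integer(seed))
  .validateSimConfig(cfg)
  class(cfg) <- "SimConfig"
  cfg
}

.validateSimConfig <- function(cfg) {
  if (any(cfg$chromSizes$size_mb <= 0)) stop("chromosome sizes must be > 0")
  if (cfg$nMarkers < 2 * nrow(cfg$chromSizes))
    stop("nMarkers must be at least 2 per chromosome")
  if (cfg$fst < 0 || cfg$fst >= 1) stop("fst must be in [0, 1)")
  if (cfg$founderCount < 1) stop("founderCount must be >= 1")
  if (cfg$ldScaleMb < 0) stop("ldScaleMb must be >= 0")
  if (cfg$missingRate < 0 || cfg$missingRate >= 1)
    stop("missingRate must be in [0, 1)")
  for (t in cfg$traits) {
    if (t$h2 < 0 || t$h2 > 1) stop("trait h2 must be in [0, 1]")
    if (t$h2 > 0 && t$nQtl < 1)
      stop("trait '", t$name, "': h2 > 0 requires nQtl >= 1")
  }
  invisible(cfg)
}

# Marker map: counts proportional to chromosome size, positions jittered
# around an even grid. Deterministic given the seed already set.
.markerMap <- function(cfg) {
  sizes <- cfg$chromSizes$size_mb
  raw <- cfg$nMarkers * sizes / sum(sizes)
  counts <- pmax(2L, floor(raw))
  rem <- cfg$nMarkers - sum(counts)
  if (rem > 0) {
    extra <- order(raw - floor(raw), decreasing = TRUE)
    counts[extra[seq_len(rem)]] <- counts[extra[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    cut <- order(counts, decreasing = TRUE)
    for (i in cut) {
      if (rem == 0) break
      take <- min(counts[i] - 2L, -rem)
      counts[i] <- counts[i] - take
      rem <- rem + take
    }
  }
  maps <- lapply(seq_along(sizes), function(ci) {
    nc <- counts[ci]
    L <- sizes[ci]
    step <- L / nc
    pos <- (seq_len(nc) - 0.5) * step +
      runif(nc, -0.5, 0.5) * cfg$jitter * step
    pos <- sort(pmin(pmax(pos, step * 1e-3), L - step * 1e-3))
    bp <- round(pos * 1e6)
    while (anyDuplicated(bp)) bp[duplicated(bp)] <- bp[duplicated(bp)] + 1L
    data.frame(chrom = cfg$chromSizes$chrom[ci], pos_bp = as.integer(bp))
  })
  map <- do.call(rbind, maps)
  map <- data.frame(marker_id = sprintf("M%05d", seq_len(nrow(map))),
                    chrom = map$chrom, pos_bp = map$pos_bp)
  rownames(map) <- NULL
  map
}

#' Simulate a marker map and candidate catalog
#'
#' Draws marker positions near-uniformly per chromosome (counts
#' proportional to chromosome size, positions jittered around an even
#' grid) and attaches catalog annotations: Beta-distributed missing rates,
#' categorical mapping-quality classes (mostly clean classes 1-3), a MAF
#' drawn from a polymorphism-enriched Beta spectrum on \[0, 0.5\], and a
#' Poisson count of secondary polymorphisms in the amplicon. The catalog
#' feeds panel-selection workflows; [simulatePopulation()] regenerates the
#' same map from the same seed and replaces the catalog MAF with realized
#' site frequencies.
#'
#' @param config a [simConfig()] object.
#' @return list with `map` (marker_id, chrom, pos_bp) and `catalog`
#'   (map columns plus `missing_rate`, `maf`, `map_class`,
#'   `n_extra_polymorphisms`).
#' @export
simulateMarkers <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  map <- .markerMap(config)
  m <- nrow(map)
  catalog <- data.frame(
    map,
    missing_rate = rbeta(m, 1.5, 8),
    maf = 0.5 * rbeta(m, 2, 1.2),
    map_class = sample(1:5, m, replace = TRUE,
                       prob = c(0.45, 0.25, 0.15, 0.10, 0.05)),
    n_extra_polymorphisms = rpois(m, 0.24))
  list(map = map, catalog = catalog)
}

# One meiosis for every individual at once: per chromosome, a random start
# haplotype and Haldane-model switches between adjacent markers
# (r = 0.5 (1 - exp(-2 d_Morgan)), no interference).
.meiosisAll <- function(H1, H2, chromIdx, recomb) {
  G <- H1
  n <- nrow(H1)
  for (ci in seq_along(chromIdx)) {
    idx <- chromIdx[[ci]]
    state <- rbinom(n, 1L, 0.5)
    sel <- state == 1L
    G[sel, idx[1]] <- H2[sel, idx[1]]
    L <- length(idx)
    if (L > 1) {
      r <- recomb[[ci]]
      for (j in 2:L) {
        state <- (state + (runif(n) < r[j - 1L])) %% 2L
        sel <- state == 1L
        G[sel, idx[j]] <- H2[sel, idx[j]]
        G[!sel, idx[j]] <- H1[!sel, idx[j]]
      }
    }
  }
  G
}

#' Simulate a station-structured breeding population
#'
#' Generates genotypes for `nAccessions` inbred-line-like accessions:
#' station allele frequencies drift from a common ancestral frequency
#' under a Balding-Nichols model with divergence `fst`; each station
#' contributes a small set of inbred founders drawn from its frequencies;
#' each accession is a biparental cross between two founders of its
#' station followed by `selfingGenerations` rounds of selfing with
#' Haldane-model recombination, leaving residual heterozygosity of about
#' `2^-selfingGenerations`. Missing calls are injected completely at
#' random. Accessions are assigned evenly to stations and harvest years.
#'
#' @param config a [simConfig()] object.
#' @return list with `gd` (a [GenotypeData-class]) and `truth` (class
#'   `"SimTruth"`: the marker `map`, the `catalog` with realized MAF,
#'   `station` labels, `trueDosage` without missing calls (accessions x
#'   sites), ancestral and per-station allele frequencies, and the
#'   config).
#' @export
simulatePopulation <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  mk <- simulateMarkers(config)   # seeds the stream; map reproduced exactly
  map <- mk$map
  m <- nrow(map)
  n <- config$nAccessions
  S <- config$nStations
  stations <- sprintf("ST%02d", seq_len(S))
  pAnc <- runif(m, 0.1, 0.9)
  Fst <- config$fst
  pStation <- if (Fst > 0) {
    t(vapply(seq_len(S), function(s)
      rbeta(m, pAnc * (1 - Fst) / Fst, (1 - pAnc) * (1 - Fst) / Fst),
      numeric(m)))
  } else {
    matrix(pAnc, nrow = S, ncol = m, byrow = TRUE)
  }
  pStation <- pmin(pmax(pStation, 1e-4), 1 - 1e-4)
  chromIdx <- split(seq_len(m), map$chrom)[unique(map$chrom)]
  # Founder haplotypes: thresholded latent Gaussian with distance-decaying
  # autocorrelation, so marginal allele frequencies follow the
  # Balding-Nichols station frequencies while nearby sites are in LD
  # (decay length ldScaleMb).
  founders <- lapply(seq_len(S), function(s) {
    nf <- config$founderCount
    Z <- matrix(0, nf, m)
    for (idx in chromIdx) {
      rho <- if (config$ldScaleMb > 0)
        exp(-diff(map$pos_bp[idx]) / 1e6 / config$ldScaleMb)
      else rep(0, length(idx) - 1L)
      Z[, idx[1]] <- rnorm(nf)
      for (j in seq_along(rho))
        Z[, idx[j + 1L]] <- rho[j] * Z[, idx[j]] +
          sqrt(1 - rho[j]^2) * rnorm(nf)
    }
    thr <- matrix(stats::qnorm(pStation[s, ]), nf, m, byrow = TRUE)
    matrix(as.integer(Z < thr), nf, m)
  })
  accStation <- rep_len(seq_len(S), n)
  accYear <- sample(rep_len(config$years, n))
  p1 <- integer(n); p2 <- integer(n)
  for (i in seq_len(n)) {
    pick <- if (config$founderCount > 1)
      sample.int(config$founderCount, 2) else c(1L, 1L)
    p1[i] <- pick[1]; p2[i] <- pick[2]
  }
  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  for (s in seq_len(S)) {
    rows <- which(accStation == s)
    H1[rows, ] <- founders[[s]][p1[rows], , drop = FALSE]
    H2[rows, ] <- founders[[s]][p2[rows], , drop = FALSE]
  }
  recomb <- lapply(chromIdx, function(idx) {
    dM <- diff(map$pos_bp[idx]) / 1e6 * config$recombRateCmPerMb / 100
    0.5 * (1 - exp(-2 * dM))
  })
  for (g in seq_len(config$selfingGenerations)) {
    G1 <- .meiosisAll(H1, H2, chromIdx, recomb)
    G2 <- .meiosisAll(H1, H2, chromIdx, recomb)
    H1 <- G1; H2 <- G2
  }
  trueDosage <- H1 + H2
  D <- t(trueDosage)
  if (config$missingRate > 0) {
    miss <- matrix(runif(length(D)) < config$missingRate, nrow(D))
    D[miss] <- NA_real_
  }
  p <- colMeans(trueDosage) / 2
  catalog <- mk$catalog
  catalog$maf <- pmin(p, 1 - p)
  accInfo <- data.frame(accession = sprintf("ACC%04d", seq_len(n)),
                        station = stations[accStation],
                        year = accYear)
  siteInfo <- data.frame(map, ref = "A", alt = "G")
  colnames(D) <- accInfo$accession
  gd <- GenotypeData(D, siteInfo, accInfo)
  truth <- structure(
    list(map = map, catalog = catalog, station = accInfo$station,
         year = accYear, trueDosage = trueDosage, pAncestral = pAnc,
         pStation = pStation, founders = founders,
         parents = cbind(p1 = p1, p2 = p2), traits = list(),
         config = config),
    class = "SimTruth")
  list(gd = gd, truth = truth)
}

#' Simulate polygenic phenotypes with station and year shifts
#'
#' For each configured trait, draws `nQtl` QTL among the markers with
#' standard-normal additive effects, forms the true breeding value
#' `g = M a` from the complete (pre-missingness) dosages, standardizes it,
#' and composes the within-group phenotype as
#' `sqrt(h2) std(g) + sqrt(1 - h2) N(0, 1)`, so the genetic share of the
#' within-station-year variance equals the target heritability. Station
#' and station-by-year location shifts and a mild log-normal scale factor
#' are then applied, emulating differences in growth conditions and
#' measurement equipment between breeding stations and years.
#'
#' @param truth `SimTruth` from [simulatePopulation()].
#' @param gm the matching [GenotypeData-class].
#' @param config the [simConfig()] used for the population.
#' @return list with `pheno` (long data.frame: accession, station, year,
#'   trait, value) and `truth` updated with per-trait QTL ids, effects,
#'   breeding values `g`, and realized heritability.
#' @export
simulatePhenotypes <- function(truth, gm, config = truth$config) {
  stopifnot(inherits(truth, "SimTruth"))
  set.seed(config$seed + 1000L)
  acc <- accessionInfo(gm)
  n <- nrow(acc)
  m <- nrow(truth$map)
  stations <- sort(unique(acc$station))
  years <- sort(unique(acc$year))
  out <- list()
  for (t in config$traits) {
    if (t$h2 > 0 && t$nQtl == 0)
      stop("trait '", t$name, "': h2 > 0 requires QTL")
    if (t$nQtl >= 1) {
      # breeding values are drawn even at h2 = 0 (weight sqrt(h2) is then
      # zero) so the ground truth g is always defined
      qtlIdx <- sort(sample.int(m, t$nQtl))
      a <- rnorm(t$nQtl)
      g <- drop(truth$trueDosage[, qtlIdx, drop = FALSE] %*% a)
    } else {
      qtlIdx <- integer(0); a <- numeric(0); g <- rep(0, n)
    }
    gstd <- if (sd(g) > 0) (g - mean(g)) / sd(g) else g
    e <- rnorm(n)
    y0 <- sqrt(t$h2) * gstd + sqrt(1 - t$h2) * e
    locStation <- setNames(rnorm(length(stations), 0, t$stationEffectSd),
                           stations)
    locSY <- matrix(rnorm(length(stations) * length(years), 0,
                          t$yearEffectSd),
                    length(stations), length(years),
                    dimnames = list(stations, as.character(years)))
    scl <- if (is.null(t$scaleSdLog) || t$scaleSdLog == 0)
      matrix(1, length(stations), length(years),
             dimnames = dimnames(locSY))
    else matrix(exp(rnorm(length(stations) * length(years), 0,
                          t$scaleSdLog)),
                length(stations), length(years),
                dimnames = dimnames(locSY))
    si <- acc$station
    yi <- as.character(acc$year)
    y <- locStation[si] + locSY[cbind(si, yi)] + scl[cbind(si, yi)] * y0
    realizedH2 <- if (sd(y0) > 0) var(sqrt(t$h2) * gstd) / var(y0) else 0
    truth$traits[[t$name]] <-
      list(qtl = truth$map$marker_id[qtlIdx], effects = a, g = g,
           targetH2 = t$h2, realizedH2 = realizedH2)
    out[[t$name]] <- data.frame(accession = acc$accession,
                                station = acc$station, year = acc$year,
                                trait = t$name, value = unname(y))
  }
  list(pheno = do.call(rbind, c(out, make.row.names = FALSE)),
       truth = truth)
}

#' Write a simulated dataset as a plain-text fixture
#'
#' Emits a complete offline test fixture: genotypes as an uncompressed
#' VCFv4.2 (GT-only), phenotypes, candidate catalog, accession metadata
#' and chromosome sizes as tab-separated text, and the simulation ground
#' truth (station labels, per-trait QTL and realized heritability) as
#' JSON. [loadFixture()] reads the set back.
#'
#' @param gm a [GenotypeData-class].
#' @param pheno phenotype table (long format) or NULL.
#' @param catalog candidate catalog or NULL.
#' @param dir output directory (created if needed).
#' @param truth optional `SimTruth`; its realized heritabilities and QTL
#'   are stored in `truth.json`.
#' @param chromSizes optional chromosome-size table; defaults to the one
#'   in `truth$config`.
#' @return invisibly, the named vector of written paths.
#' @export
writeFixture <- function(gm, pheno = NULL, catalog = NULL, dir,
                         truth = NULL, chromSizes = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"))
  si <- siteInfo(gm)
  d <- dosages(gm)
  gtCode <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gtCode[d[ok] + 1]
  ref <- if ("ref" %in% names(si)) si$ref else "A"
  alt <- if ("alt" %in% names(si)) si$alt else "G"
  body <- paste(si$chrom, si$pos_bp, si$marker_id, ref, alt, ".", "PASS",
                ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", colnames(d)),
                     collapse = "\t"),
               body),
             paths["vcf"])
  tsv <- function(x, name) {
    p <- file.path(dir, name)
    write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths["accessions"] <- tsv(accessionInfo(gm), "accessions.tsv")
  if (!is.null(pheno)) paths["pheno"] <- tsv(pheno, "phenotypes.tsv")
  if (!is.null(catalog)) paths["catalog"] <- tsv(catalog, "catalog.tsv")
  if (is.null(chromSizes) && !is.null(truth))
    chromSizes <- truth$config$chromSizes
  if (!is.null(chromSizes))
    paths["chrom_sizes"] <- tsv(chromSizes, "chrom_sizes.tsv")
  if (!is.null(truth)) {
    paths["truth"] <- file.path(dir, "truth.json")
    jsonlite::write_json(
      list(station = truth$station, year = truth$year,
           traits = lapply(truth$traits, function(tr)
             list(qtl = tr$qtl, effects = tr$effects,
                  targetH2 = tr$targetH2, realizedH2 = tr$realizedH2))),
      paths["truth"], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Read back a fixture written by [writeFixture()]
#'
#' @param dir fixture directory.
#' @return list with `gd` ([GenotypeData-class] with accession metadata
#'   re-attached), and, when present, `pheno`, `catalog`, `chromSizes`,
#'   `truth`.
#' @export
loadFixture <- function(dir) {
  accPath <- file.path(dir, "accessions.tsv")
  accInfo <- if (file.exists(accPath)) read.delim(accPath) else NULL
  out <- list(gd = loadGenotypes(file.path(dir, "genotypes.vcf"),
                                 accessionInfo = accInfo))
  p <- file.path(dir, "phenotypes.tsv")
  if (file.exists(p)) out$pheno <- read.delim(p)
  p <- file.path(dir, "catalog.tsv")
  if (file.exists(p)) out$catalog <- read.delim(p)
  p <- file.path(dir, "chrom_sizes.tsv")
  if (file.exists(p)) out$chromSizes <- read.delim(p)
  p <- file.path(dir, "truth.json")
  if (file.exists(p)) out$truth <- jsonlite::read_json(p,
                                                       simplifyVector = TRUE)
  out
}
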