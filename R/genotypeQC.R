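#' Load a multi-sample genotype matrix
#'
#' Reads diploid genotypes from a VCF (GT field) or from a headered
#' tab-separated dosage table into a [GenotypeData-class]. Only biallelic
#' records are kept; multi-allelic VCF records are dropped with a warning
#' (the count is recorded in `metadata(x)$skipped_multiallelic`). Missing
#' calls (`./.`) become NA; phased and unphased genotypes are treated
#' identically.
#'
#' The dosage-table format has columns `marker_id`, `chrom`, `pos_bp`
#' (optionally `ref`, `alt`) followed by one column per accession with
#' entries 0/1/2 or NA.
#'
#' @param path path to a `.vcf`/`.vcf.gz` file or a dosage table.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage"`.
#' @param accessionInfo optional data.frame of accession metadata
#'   (`accession`, `station`, `year`) matched to sample names.
#' @return A [GenotypeData-class].
#' @export
loadGenotypes <- function(path, format = c("auto", "vcf", "dosage"),
                          accessionInfo = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "dosage"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    if (ncol(v@gt) < 2) stop("VCF contains no sample columns")
    bi <- vcfR::is.biallelic(v)
    nDropped <- sum(!bi)
    if (nDropped > 0) {
      warning(nDropped, " multi-allelic record(s) dropped")
      v <- v[bi, ]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gsub("|", "/", gt, fixed = TRUE)
    d <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    d[gt == "0/0"] <- 0
    d[gt %in% c("0/1", "1/0")] <- 1
    d[gt == "1/1"] <- 2
    fix <- vcfR::getFIX(v)
    id <- fix[, "ID"]
    noId <- is.na(id) | id == "."
    id[noId] <- paste0(fix[noId, "CHROM"], "_", fix[noId, "POS"])
    si <- data.frame(marker_id = id, chrom = fix[, "CHROM"],
                     pos_bp = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"])
  } else {
    tab <- read.delim(path, check.names = FALSE)
    .checkCols(tab, c("marker_id", "chrom", "pos_bp"), "dosage table")
    metaCols <- intersect(c("marker_id", "chrom", "pos_bp", "ref", "alt"),
                          names(tab))
    si <- tab[, metaCols, drop = FALSE]
    d <- as.matrix(tab[, setdiff(names(tab), metaCols), drop = FALSE])
    if (ncol(d) == 0) stop("dosage table contains no sample columns")
    storage.mode(d) <- "double"
    nDropped <- 0L
  }
  if (nrow(d) == 0 || all(is.na(d)))
    stop("no usable genotype calls in ", path)
  if (!is.null(accessionInfo)) {
    idx <- match(colnames(d), accessionInfo$accession)
    if (anyNA(idx))
      stop("accessionInfo lacks sample(s): ",
           paste(colnames(d)[is.na(idx)][1:5], collapse = ", "))
    accessionInfo <- accessionInfo[idx, , drop = FALSE]
    rownames(accessionInfo) <- NULL
  }
  gd <- GenotypeData(d, si, accessionInfo)
  metadata(gd)$skipped_multiallelic <- nDropped
  gd
}

#' Per-site genotype statistics
#'
#' For each site, the minor allele frequency from allele counts
#' (`p = (n_het + 2 n_homalt) / (2 n_nonmissing)`, `maf = min(p, 1 - p)`;
#' heterozygotes contribute one alternate allele, missing calls are excluded
#' from numerator and denominator), the missing-call rate, and the
#' heterozygosity rate among non-missing calls.
#'
#' @param gm a [GenotypeData-class].
#' @return data.frame with columns `marker_id`, `chrom`, `pos_bp`,
#'   `n_nonmissing`, `maf`, `missing_rate`, `het_rate`. Sites with no
#'   non-missing calls get NA statistics and a warning.
#' @examples
#' gd <- GenotypeData(matrix(c(0, 0, 0, 2), 1),
#'                    data.frame(marker_id = "m", chrom = "1H", pos_bp = 1L))
#' siteStats(gd)$maf  # 0.25
#' @export
siteStats <- function(gm) {
  d <- dosages(gm)
  n <- ncol(d)
  nMiss <- rowSums(is.na(d))
  nNon <- n - nMiss
  nHet <- rowSums(d == 1, na.rm = TRUE)
  altCount <- rowSums(d, na.rm = TRUE)
  p <- ifelse(nNon > 0, altCount / (2 * nNon), NA_real_)
  maf <- pmin(p, 1 - p)
  het <- ifelse(nNon > 0, nHet / nNon, NA_real_)
  if (any(nNon == 0))
    warning(sum(nNon == 0), " site(s) with no non-missing calls; ",
            "statistics set to NA")
  si <- siteInfo(gm)
  data.frame(marker_id = si$marker_id, chrom = si$chrom,
             pos_bp = si$pos_bp, n_nonmissing = nNon, maf = maf,
             missing_rate = nMiss / n, het_rate = het)
}

#' Filter genotype sites on missingness and heterozygosity
#'
#' Removes sites whose missing rate exceeds `maxMissing` or whose
#' heterozygosity rate exceeds `maxHet` (both strictly; a site at exactly
#' the threshold is retained). The default OR combination removes a site
#' failing either criterion, the usual QC reading for mostly-inbred
#' material; `combine = "and"` removes only sites failing both.
#'
#' @param gm a [GenotypeData-class].
#' @param maxMissing strict missing-rate threshold (default 0.5).
#' @param maxHet strict heterozygosity threshold (default 0.2).
#' @param combine `"or"` (default) or `"and"`.
#' @return The filtered [GenotypeData-class]; the removal report
#'   (data.frame `marker_id`, `missing_rate`, `het_rate`, `reason`) is in
#'   `metadata(x)$siteFilter`.
#' @export
siteFilter <- function(gm, maxMissing = 0.5, maxHet = 0.2,
                       combine = c("or", "and")) {
  combine <- match.arg(combine)
  st <- siteStats(gm)
  failMiss <- st$missing_rate > maxMissing
  failHet <- !is.na(st$het_rate) & st$het_rate > maxHet
  drop <- if (combine == "or") failMiss | failHet else failMiss & failHet
  drop <- drop | st$n_nonmissing == 0
  if (all(drop))
    stop("all sites removed; review maxMissing/maxHet thresholds")
  reason <- ifelse(failMiss & failHet, "missing+het",
                   ifelse(failMiss, "missing", "het"))
  report <- data.frame(marker_id = st$marker_id[drop],
                       missing_rate = st$missing_rate[drop],
                       het_rate = st$het_rate[drop],
                       reason = reason[drop])
  out <- gm[!drop, ]
  metadata(out)$siteFilter <-
    list(maxMissing = maxMissing, maxHet = maxHet, combine = combine,
         removed = report)
  out
}

#' Smoothed minor-allele-frequency profile along chromosomes
#'
#' Computes per-site MAF and, for each chromosome with at least `minSites`
#' sites, a LOESS curve (local linear regression with tricube weights) of
#' MAF against physical position, evaluated on an even grid with a
#' pointwise 95% interval from the local fit's standard error. Fitted
#' values are clipped to \[0, 0.5\]. An accession subset yields per-group
#' profiles (e.g. per breeding station).
#'
#' @param gm a [GenotypeData-class].
#' @param span LOESS span (default 0.3).
#' @param gridPoints evaluation grid size per chromosome (default 200).
#' @param accessions optional character vector of accession ids (or logical
#'   index) restricting the MAF computation.
#' @param minSites minimum sites per chromosome for smoothing (default 10);
#'   chromosomes below it contribute raw points only.
#' @return list with `points` (chrom, pos_mb, maf), `curve` (chrom, pos_mb,
#'   fit, ci_half), and `skipped` (chromosomes without a curve).
#' @export
mafProfile <- function(gm, span = 0.3, gridPoints = 200, accessions = NULL,
                       minSites = 10) {
  if (!is.null(accessions)) gm <- gm[, accessions]
  st <- siteStats(gm)
  st <- st[!is.na(st$maf) & st$chrom != "Un", , drop = FALSE]
  pts <- data.frame(chrom = st$chrom, pos_mb = st$pos_bp / 1e6,
                    maf = st$maf)
  curves <- list()
  skipped <- character()
  for (ch in unique(pts$chrom)) {
    sub <- pts[pts$chrom == ch, , drop = FALSE]
    if (nrow(sub) < minSites) {
      skipped <- c(skipped, ch)
      next
    }
    fit <- loess(maf ~ pos_mb, data = sub, span = span, degree = 1,
                 family = "gaussian")
    grid <- seq(min(sub$pos_mb), max(sub$pos_mb), length.out = gridPoints)
    pr <- predict(fit, newdata = data.frame(pos_mb = grid), se = TRUE)
    curves[[ch]] <- data.frame(
      chrom = ch, pos_mb = grid,
      fit = pmin(pmax(pr$fit, 0), 0.5),
      ci_half = qnorm(0.975) * pr$se.fit)
  }
  list(points = pts,
       curve = if (length(curves)) do.call(rbind, c(curves,
                                                    make.row.names = FALSE))
               else data.frame(chrom = character(), pos_mb = numeric(),
                               fit = numeric(), ci_half = numeric()),
       skipped = skipped)
}
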