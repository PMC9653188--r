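#' @include AllGenerics.R
NULL

#' Configuration for core-panel marker selection
#'
#' Holds the thresholds used by [filterCandidates()] and [selectCoreSet()].
#' Candidates are kept when their missing rate is strictly below `maxMissing`
#' and their mapping-quality class is in `allowedClasses` (class 1 = cleanest
#' mapping). Chromosomes are then tiled into consecutive windows of
#' `targetSpacingMb`; within each window the highest-MAF candidate passing the
#' applicable minor-allele-frequency floor is selected. Windows holding at
#' least `denseMinCount` candidates use the `minMafDense` floor, marker-poor
#' windows use the relaxed `minMafSparse` floor so that coverage is retained
#' in low-polymorphism regions.
#'
#' @slot maxMissing numeric(1), strict upper bound on candidate missing rate.
#' @slot allowedClasses integer vector of admissible mapping-quality classes.
#' @slot targetSpacingMb numeric(1), window length in Mb (target marker
#'   spacing).
#' @slot minMafDense numeric(1), MAF floor in marker-rich windows.
#' @slot minMafSparse numeric(1), relaxed MAF floor in marker-poor windows.
#' @slot denseMinCount integer(1), candidate count at or above which a window
#'   counts as marker-rich.
#' @export
setClass("SelectionConfig",
  slots = c(maxMissing = "numeric", allowedClasses = "integer",
            targetSpacingMb = "numeric", minMafDense = "numeric",
            minMafSparse = "numeric", denseMinCount = "integer"))

setValidity("SelectionConfig", function(object) {
  msg <- character()
  if (length(object@maxMissing) != 1 || object@maxMissing < 0 ||
      object@maxMissing > 1)
    msg <- c(msg, "maxMissing must be a single value in [0, 1]")
  if (length(object@allowedClasses) < 1 || any(object@allowedClasses < 1))
    msg <- c(msg, "allowedClasses must be ordinals >= 1")
  if (length(object@targetSpacingMb) != 1 || object@targetSpacingMb <= 0)
    msg <- c(msg, "targetSpacingMb must be a single positive value")
  if (object@minMafSparse > object@minMafDense)
    msg <- c(msg, "minMafSparse must not exceed minMafDense")
  if (object@denseMinCount < 1L)
    msg <- c(msg, "denseMinCount must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Create a selection configuration
#'
#' @param maxMissing strict upper bound on candidate missing rate
#'   (default 0.3: candidates with missing rate below 0.3 pass).
#' @param allowedClasses admissible mapping-quality classes (default 1:3,
#'   markers with no or little off-target/homoeologous interference).
#' @param targetSpacingMb selection window length in Mb, the target marker
#'   spacing (default 6, giving roughly one marker per 6 Mb as in a
#'   barley-scale panel).
#' @param minMafDense MAF floor applied in marker-rich windows (default 0.1).
#' @param minMafSparse relaxed MAF floor for marker-poor windows
#'   (default 0.01).
#' @param denseMinCount candidate count from which a window counts as
#'   marker-rich (default 3).
#' @return A [SelectionConfig-class] object.
#' @examples
#' selectionConfig(targetSpacingMb = 15)
#' @export
selectionConfig <- function(maxMissing = 0.3, allowedClasses = 1:3,
                            targetSpacingMb = 6, minMafDense = 0.1,
                            minMafSparse = 0.01, denseMinCount = 3L) {
  new("SelectionConfig", maxMissing = maxMissing,
      allowedClasses = as.integer(allowedClasses),
      targetSpacingMb = targetSpacingMb, minMafDense = minMafDense,
      minMafSparse = minMafSparse, denseMinCount = as.integer(denseMinCount))
}

setMethod("show", "SelectionConfig", function(object) {
  cat("SelectionConfig\n",
      sprintf("  missing rate < %.3g; classes {%s}\n", object@maxMissing,
              paste(object@allowedClasses, collapse = ",")),
      sprintf("  window %.3g Mb; MAF floor %.3g (dense, >= %d candidates) / %.3g (sparse)\n",
              object@targetSpacingMb, object@minMafDense,
              object@denseMinCount, object@minMafSparse), sep = "")
})

#' A core marker set
#'
#' An ordered panel of markers selected from a candidate catalog, sorted by
#' chromosome and position (unplaced "Un" markers last). The `markers` slot
#' keeps all catalog columns so downstream summaries (secondary
#' polymorphisms, platform statistics) can be computed from the object alone.
#'
#' @slot markers data.frame of selected catalog rows.
#' @slot name character(1), panel name (e.g. "HvCoreSet_v1").
#' @slot selectionInfo list of bookkeeping from [selectCoreSet()] (window
#'   gaps, floors used); empty for manually constructed sets.
#' @export
setClass("CoreSet",
  slots = c(markers = "data.frame", name = "character",
            selectionInfo = "list"))

setValidity("CoreSet", function(object) {
  m <- object@markers
  msg <- character()
  req <- c("marker_id", "chrom", "pos_bp")
  if (!all(req %in% names(m)))
    msg <- c(msg, paste("markers must have columns",
                        paste(req, collapse = ", ")))
  else {
    if (anyDuplicated(m$marker_id))
      msg <- c(msg, "duplicate marker_id in core set")
    placed <- m$chrom != "Un"
    if (any(placed & is.na(m$pos_bp)))
      msg <- c(msg, "placed markers must have pos_bp")
    bychrom <- split(m$pos_bp[placed], m$chrom[placed])
    if (!all(vapply(bychrom, function(p) !is.unsorted(p), logical(1))))
      msg <- c(msg, "markers must be sorted by position within chromosome")
  }
  if (length(object@name) != 1) msg <- c(msg, "name must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a CoreSet from a marker table
#'
#' @param markers data.frame with at least `marker_id`, `chrom`, `pos_bp`
#'   (NA position allowed only for chromosome "Un"); rows are re-sorted by
#'   (chrom, pos_bp).
#' @param name panel name.
#' @param selectionInfo optional bookkeeping list.
#' @return A [CoreSet-class] object.
#' @export
CoreSet <- function(markers, name = "CoreSet_v1", selectionInfo = list()) {
  .checkCols(markers, c("marker_id", "chrom", "pos_bp"), "core marker table")
  ord <- order(markers$chrom == "Un", markers$chrom, markers$pos_bp)
  markers <- markers[ord, , drop = FALSE]
  rownames(markers) <- NULL
  new("CoreSet", markers = markers, name = name,
      selectionInfo = selectionInfo)
}

setMethod("show", "CoreSet", function(object) {
  m <- object@markers
  cat(sprintf("CoreSet '%s': %d markers on %d chromosome(s)\n", object@name,
              nrow(m), length(unique(m$chrom[m$chrom != "Un"]))))
  if (any(m$chrom == "Un"))
    cat(sprintf("  (%d unplaced)\n", sum(m$chrom == "Un")))
})

#' @describeIn CoreSet the selected marker table.
#' @param x a `CoreSet`.
#' @export
setMethod("coreMarkers", "CoreSet", function(x) x@markers)

#' @describeIn CoreSet the panel name.
#' @export
setMethod("setName", "CoreSet", function(x) x@name)

#' Platform summary of a core marker set
#'
#' Per-chromosome and total interval/coverage statistics of a marker panel:
#' marker counts, maximum and mean adjacent-marker intervals, terminal marker
#' positions, covered size (last minus first marker), reference chromosome
#' size, and the percentage of the reference spanned. Totals count unplaced
#' markers (and unplaced reference length) in the marker total and the
#' denominator of total coverage, while interval statistics run over placed
#' chromosomes only, each contributing (n - 1) intervals.
#'
#' @slot perChrom data.frame with one row per placed chromosome: `chrom`,
#'   `n_markers`, `max_interval_mb`, `mean_interval_mb`, `start_mb`,
#'   `end_mb`, `cover_size_mb`, `refseq_mb`, `coverage_pct`.
#' @slot totals named list: `total_markers`, `n_unplaced`, `total_cover_mb`,
#'   `total_refseq_mb`, `total_coverage_pct`, `overall_mean_interval_mb`,
#'   `overall_max_interval_mb`.
#' @slot decimals integer(1), decimals used when rounding reported values
#'   (half-up).
#' @export
setClass("PlatformSummary",
  slots = c(perChrom = "data.frame", totals = "list", decimals = "integer"))

setValidity("PlatformSummary", function(object) {
  pc <- object@perChrom
  msg <- character()
  req <- c("chrom", "n_markers", "max_interval_mb", "mean_interval_mb",
           "start_mb", "end_mb", "cover_size_mb", "refseq_mb",
           "coverage_pct")
  if (!all(req %in% names(pc)))
    msg <- c(msg, "perChrom lacks required columns")
  else {
    cp <- pc$coverage_pct
    if (any(!is.na(cp) & (cp < 0 | cp > 100)))
      msg <- c(msg, "coverage_pct must lie in [0, 100]")
    tol <- 10^(-object@decimals) * pmax(1, pc$n_markers)
    ok <- is.na(pc$mean_interval_mb) |
      abs(pc$mean_interval_mb * (pc$n_markers - 1) - pc$cover_size_mb) <= tol
    if (!all(ok))
      msg <- c(msg, "mean interval inconsistent with cover size")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PlatformSummary", function(object) {
  cat("PlatformSummary (values rounded half-up to", object@decimals,
      "decimal(s))\n")
  print(object@perChrom, row.names = FALSE)
  t <- object@totals
  f <- function(v) formatC(v, format = "f", digits = object@decimals)
  cat(sprintf(
    "Total: %d markers (%d unplaced); cover %s / %s Mb = %s%%; interval mean %s, max %s Mb\n",
    t$total_markers, t$n_unplaced, f(t$total_cover_mb),
    f(t$total_refseq_mb), f(t$total_coverage_pct),
    f(t$overall_mean_interval_mb), f(t$overall_max_interval_mb)))
})

#' @describeIn PlatformSummary per-chromosome statistics table.
#' @param x a `PlatformSummary`.
#' @export
setMethod("perChromSummary", "PlatformSummary", function(x) x@perChrom)

#' @describeIn PlatformSummary totals as a named list.
#' @export
setMethod("platformTotals", "PlatformSummary", function(x) x@totals)

#' Multi-sample genotype matrix
#'
#' A [SummarizedExperiment-class] holding a biallelic genotype dosage matrix:
#' assay `"dosage"` has one row per site and one column per accession, with
#' entries 0/1/2 (count of the alternate allele) or NA for missing calls.
#' `rowData` carries the site metadata (`marker_id`, `chrom`, `pos_bp` and,
#' when read from VCF, `ref`/`alt`), `colData` the accession metadata
#' (`accession` plus optional `station` and `year`).
#'
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (!"dosage" %in% assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    v <- d[!is.na(d)]
    if (length(v) && !all(v %in% c(0, 1, 2)))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  rd <- rowData(object)
  if (!all(c("chrom", "pos_bp") %in% colnames(rd)))
    msg <- c(msg, "rowData must have 'chrom' and 'pos_bp'")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage numeric matrix, sites x accessions, entries 0/1/2/NA.
#' @param siteInfo data.frame with one row per site; must contain
#'   `marker_id`, `chrom`, `pos_bp`.
#' @param accessionInfo optional data.frame with one row per accession
#'   (column `accession` plus e.g. `station`, `year`); defaults to the
#'   dosage column names.
#' @return A [GenotypeData-class] object.
#' @export
GenotypeData <- function(dosage, siteInfo, accessionInfo = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  .checkCols(siteInfo, c("marker_id", "chrom", "pos_bp"), "site metadata")
  if (nrow(siteInfo) != nrow(dosage))
    stop("siteInfo rows must match dosage rows")
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("ACC%04d", seq_len(ncol(dosage)))
  if (is.null(accessionInfo))
    accessionInfo <- data.frame(accession = colnames(dosage))
  if (nrow(accessionInfo) != ncol(dosage))
    stop("accessionInfo rows must match dosage columns")
  rownames(dosage) <- siteInfo$marker_id
  se <- SummarizedExperiment(assays = list(dosage = dosage),
                             rowData = siteInfo, colData = accessionInfo)
  new("GenotypeData", se)
}

setMethod("show", "GenotypeData", function(object) {
  d <- assay(object, "dosage")
  cat(sprintf("GenotypeData: %d sites x %d accessions (%.1f%% missing)\n",
              nrow(d), ncol(d), 100 * mean(is.na(d))))
  cd <- colData(object)
  if ("station" %in% colnames(cd))
    cat("  stations:", paste(sort(unique(cd$station)), collapse = " "), "\n")
  if ("year" %in% colnames(cd))
    cat("  years:", paste(sort(unique(cd$year)), collapse = " "), "\n")
})

#' @describeIn GenotypeData the sites x accessions dosage matrix.
#' @param x a `GenotypeData`.
#' @export
setMethod("dosages", "GenotypeData",
          function(x) assay(x, "dosage"))

#' @describeIn GenotypeData site metadata as a data.frame.
#' @export
setMethod("siteInfo", "GenotypeData",
          function(x) as.data.frame(rowData(x)))

#' @describeIn GenotypeData accession metadata as a data.frame.
#' @export
setMethod("accessionInfo", "GenotypeData",
          function(x) as.data.frame(colData(x)))

#' Fitted ridge-regression BLUP model
#'
#' Mixed model `y = 1 mu + M u + e` with `u ~ N(0, I sigma2u)`,
#' `e ~ N(0, I sigma2e)`, fitted by [fitRRBlup()]. Marker columns are
#' centered by their training means (stored in `siteMeans` and re-applied at
#' prediction time); `lambda = sigma2e / sigma2u` is the ridge parameter.
#'
#' @slot mu numeric(1), generalized-least-squares intercept.
#' @slot effects numeric, one BLUP effect per training site.
#' @slot sigma2u,sigma2e numeric(1), REML variance components.
#' @slot lambda numeric(1), `sigma2e / sigma2u`.
#' @slot siteIds character, training site identifiers (effect order).
#' @slot siteMeans numeric, training-mean dosages used for centering and
#'   missing-value imputation.
#' @slot meanDiagK numeric(1), mean diagonal of the centered marker
#'   cross-product `M M'` (used to express genetic variance on the
#'   phenotypic scale).
#' @slot zeroVariance logical(1), TRUE when the training phenotype had no
#'   variance and the model degenerates to the intercept.
#' @export
setClass("RRBlupModel",
  slots = c(mu = "numeric", effects = "numeric", sigma2u = "numeric",
            sigma2e = "numeric", lambda = "numeric", siteIds = "character",
            siteMeans = "numeric", meanDiagK = "numeric",
            zeroVariance = "logical"))

setValidity("RRBlupModel", function(object) {
  msg <- character()
  if (length(object@effects) != length(object@siteIds))
    msg <- c(msg, "one effect per training site required")
  if (length(object@lambda) != 1 || object@lambda <= 0)
    msg <- c(msg, "lambda must be a single positive value")
  if (object@sigma2u < 0 || object@sigma2e < 0)
    msg <- c(msg, "variance components must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RRBlupModel", function(object) {
  cat(sprintf("RRBlupModel: %d markers; mu = %.4g\n",
              length(object@effects), object@mu))
  cat(sprintf("  sigma2u = %.4g, sigma2e = %.4g, lambda = %.4g, h2 = %.3f\n",
              object@sigma2u, object@sigma2e, object@lambda,
              heritability(object)))
  if (object@zeroVariance)
    cat("  (degenerate: zero phenotypic variance in training data)\n")
})

#' @describeIn RRBlupModel per-marker BLUP effects (named by site id).
#' @param object an `RRBlupModel`.
#' @export
setMethod("markerEffects", "RRBlupModel",
          function(object) setNames(object@effects, object@siteIds))

#' @describeIn RRBlupModel named vector of `sigma2u`, `sigma2e`, `lambda`.
#' @export
setMethod("varianceComponents", "RRBlupModel", function(object)
  c(sigma2u = object@sigma2u, sigma2e = object@sigma2e,
    lambda = object@lambda))

#' @describeIn RRBlupModel genomic heritability estimate
#'   `sigma2u * meanDiag(MM') / (sigma2u * meanDiag(MM') + sigma2e)`.
#' @export
setMethod("heritability", "RRBlupModel", function(object) {
  vg <- object@sigma2u * object@meanDiagK
  if (vg + object@sigma2e <= 0) return(0)
  vg / (vg + object@sigma2e)
})
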