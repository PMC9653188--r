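#' Read a candidate-marker catalog
#'
#' Tab-separated with a header; required columns `marker_id`, `chrom`,
#' `pos_bp`, `missing_rate`, `maf`, `map_class`; optional
#' `n_extra_polymorphisms`. `pos_bp` may be empty only for unplaced
#' markers (`chrom == "Un"`).
#'
#' @param path file path.
#' @return data.frame.
#' @export
readMarkerCatalog <- function(path) {
  x <- read.delim(path)
  .checkCols(x, c("marker_id", "chrom", "pos_bp", "missing_rate", "maf",
                  "map_class"), basename(path))
  x$pos_bp <- as.integer(x$pos_bp)
  x$map_class <- as.integer(x$map_class)
  x
}

#' Read a chromosome-size table
#'
#' Tab-separated with header columns `chrom` and `size_mb`; an optional
#' `"Un"` row carries the unplaced reference length.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readChromSizes <- function(path) {
  x <- read.delim(path)
  .checkCols(x, c("chrom", "size_mb"), basename(path))
  x
}

#' Read a long-format phenotype table
#'
#' Tab-separated with header columns `accession`, `station`, `year`,
#' `trait`, `value`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readPhenotypes <- function(path) {
  x <- read.delim(path)
  .checkCols(x, c("accession", "station", "year", "trait", "value"),
             basename(path))
  x
}

#' Write a core marker set as tab-separated text
#'
#' @param core a [CoreSet-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeCoreSet <- function(core, path) {
  write.table(coreMarkers(core), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a platform summary as tab-separated text
#'
#' Emits the per-chromosome table followed by a `Total` row mirroring the
#' platform-summary column order.
#'
#' @param ps a [PlatformSummary-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writePlatformSummary <- function(ps, path) {
  pc <- perChromSummary(ps)
  t <- platformTotals(ps)
  total <- data.frame(
    chrom = "Total", n_markers = t$total_markers,
    max_interval_mb = t$overall_max_interval_mb,
    mean_interval_mb = t$overall_mean_interval_mb,
    start_mb = NA_real_, end_mb = NA_real_,
    cover_size_mb = t$total_cover_mb, refseq_mb = t$total_refseq_mb,
    coverage_pct = t$total_coverage_pct)
  write.table(rbind(pc, total), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
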