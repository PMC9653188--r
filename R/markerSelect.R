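#' Filter a candidate-marker catalog
#'
#' Keeps candidates whose missing rate is strictly below
#' `config@maxMissing` and whose mapping-quality class is one of
#' `config@allowedClasses`. Input order is preserved. Rows with a missing
#' rate outside \[0, 1\], a MAF outside \[0, 0.5\] or a mapping class below 1
#' are rejected with an error naming the offending rows.
#'
#' @param candidates data.frame with columns `marker_id`, `chrom`, `pos_bp`,
#'   `missing_rate`, `maf`, `map_class` (and optionally
#'   `n_extra_polymorphisms`). `pos_bp` may be NA only for `chrom == "Un"`.
#' @param config a [SelectionConfig-class]; see [selectionConfig()].
#' @return The retained subset of `candidates`, original order.
#' @examples
#' cat <- data.frame(marker_id = c("a", "b", "c"), chrom = "1H",
#'                   pos_bp = c(1e6, 2e6, 3e6),
#'                   missing_rate = c(0.29, 0.30, 0.05),
#'                   maf = c(0.2, 0.3, 0.4), map_class = c(3L, 1L, 4L))
#' filterCandidates(cat, selectionConfig())  # keeps only "a"
#' @export
filterCandidates <- function(candidates, config = selectionConfig()) {
  .checkCols(candidates,
             c("marker_id", "chrom", "pos_bp", "missing_rate", "maf",
               "map_class"), "candidate catalog")
  if (nrow(candidates) == 0) stop("candidate catalog is empty")
  bad <- which(!is.finite(candidates$missing_rate) |
                 candidates$missing_rate < 0 | candidates$missing_rate > 1 |
                 !is.finite(candidates$maf) | candidates$maf < 0 |
                 candidates$maf > 0.5 | candidates$map_class < 1)
  if (length(bad))
    stop("malformed catalog row(s): ",
         paste(candidates$marker_id[head(bad, 10)], collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  noPos <- candidates$chrom != "Un" & is.na(candidates$pos_bp)
  if (any(noPos))
    stop("placed candidates without pos_bp: ",
         paste(candidates$marker_id[head(which(noPos), 10)],
               collapse = ", "))
  keep <- candidates$missing_rate < config@maxMissing &
    candidates$map_class %in% config@allowedClasses
  out <- candidates[keep, , drop = FALSE]
  if (nrow(out) == 0)
    message("filterCandidates: no candidates pass the filters")
  rownames(out) <- NULL
  out
}

#' Select a core marker set by windowed tiling
#'
#' Tiles each chromosome into consecutive windows of
#' `config@targetSpacingMb` and, within each non-empty window, selects the
#' candidate with the highest minor allele frequency among those passing the
#' applicable MAF floor (`minMafDense` in windows with at least
#' `denseMinCount` candidates, `minMafSparse` otherwise, so marker-poor
#' regions keep representation). Ties on MAF are broken by lower missing
#' rate, then lower mapping class, then lower position, then marker id, so
#' the result does not depend on input row order. The first and last
#' candidates of each chromosome are always retained to maximise terminal
#' coverage. Unplaced ("Un") candidates passing the dense MAF floor are kept
#' as-is.
#'
#' @param filtered data.frame of candidates, typically the output of
#'   [filterCandidates()].
#' @param chromSizes data.frame with columns `chrom` and `size_mb`; must
#'   cover every placed chromosome present in `filtered` (an "Un" row, if
#'   present, is ignored here).
#' @param config a [SelectionConfig-class].
#' @param name name of the resulting panel.
#' @return A [CoreSet-class]. Windows that contain candidates but none
#'   passing the MAF floor raise a warning and are recorded (with entirely
#'   empty windows) in the object's `selectionInfo$gaps`.
#' @export
selectCoreSet <- function(filtered, chromSizes, config = selectionConfig(),
                          name = "CoreSet_v1") {
  .checkCols(filtered, c("marker_id", "chrom", "pos_bp", "missing_rate",
                         "maf", "map_class"), "filtered catalog")
  .checkCols(chromSizes, c("chrom", "size_mb"), "chromosome size table")
  placed <- filtered[filtered$chrom != "Un", , drop = FALSE]
  unplaced <- filtered[filtered$chrom == "Un", , drop = FALSE]
  chroms <- unique(placed$chrom)
  missing <- setdiff(chroms, chromSizes$chrom)
  if (length(missing))
    stop("chromosome(s) absent from chromSizes: ",
         paste(missing, collapse = ", "))
  spacing <- config@targetSpacingMb
  gaps <- list()
  picked <- list()
  for (ch in chroms) {
    cand <- placed[placed$chrom == ch, , drop = FALSE]
    # total tie-break order: MAF desc, then missing, class, position, id
    cand <- cand[order(-cand$maf, cand$missing_rate, cand$map_class,
                       cand$pos_bp, cand$marker_id), , drop = FALSE]
    sizeMb <- chromSizes$size_mb[match(ch, chromSizes$chrom)]
    win <- pmin(floor(cand$pos_bp / 1e6 / spacing),
                max(0, ceiling(sizeMb / spacing) - 1))
    nWin <- max(0, ceiling(sizeMb / spacing))
    sel <- logical(nrow(cand))
    for (w in unique(win)) {
      inWin <- which(win == w)
      floorMaf <- if (length(inWin) >= config@denseMinCount)
        config@minMafDense else config@minMafSparse
      pass <- inWin[cand$maf[inWin] >= floorMaf]
      if (length(pass) == 0) {
        warning(sprintf(
          "chromosome %s window %d (%.1f-%.1f Mb): no candidate passes the MAF floor",
          ch, w + 1, w * spacing, (w + 1) * spacing))
        gaps[[length(gaps) + 1L]] <-
          data.frame(chrom = ch, window = w + 1L, reason = "maf_floor")
        next
      }
      sel[pass[1L]] <- TRUE  # cand is in preference order
    }
    emptyWin <- setdiff(seq_len(nWin) - 1L, unique(win))
    if (length(emptyWin))
      gaps[[length(gaps) + 1L]] <-
        data.frame(chrom = ch, window = emptyWin + 1L,
                   reason = "no_candidates")
    # terminal markers retained regardless of MAF competition
    sel[which.min(cand$pos_bp)] <- TRUE
    sel[which.max(cand$pos_bp)] <- TRUE
    picked[[ch]] <- cand[sel, , drop = FALSE]
  }
  if (nrow(unplaced)) {
    keepUn <- unplaced$maf >= config@minMafDense
    picked[["Un"]] <- unplaced[keepUn, , drop = FALSE]
  }
  out <- do.call(rbind, picked)
  if (is.null(out) || nrow(out) == 0)
    stop("no markers selected; review the selection configuration")
  out <- out[!duplicated(out$marker_id), , drop = FALSE]
  CoreSet(out, name = name,
          selectionInfo = list(
            gaps = if (length(gaps)) do.call(rbind, gaps)
                   else data.frame(chrom = character(), window = integer(),
                                   reason = character()),
            config = config))
}

# Shared platform arithmetic. `placed`: data.frame(chrom, n_markers,
# start_mb, end_mb, refseq_mb[, max_interval_mb]).
.platformFromChromTable <- function(placed, nUnplaced, unplacedRefMb,
                                    decimals) {
  r <- function(x) roundHalfUp(x, decimals)
  hasMax <- "max_interval_mb" %in% names(placed)
  cover <- placed$end_mb - placed$start_mb
  few <- placed$n_markers < 2
  if (any(few))
    warning("chromosome(s) with fewer than 2 markers: ",
            paste(placed$chrom[few], collapse = ", "),
            "; interval fields reported as NA")
  meanInt <- ifelse(few, NA_real_, cover / (placed$n_markers - 1))
  coverage <- 100 * cover / placed$refseq_mb
  perChrom <- data.frame(
    chrom = placed$chrom,
    n_markers = as.integer(placed$n_markers),
    max_interval_mb = if (hasMax) r(placed$max_interval_mb) else NA_real_,
    mean_interval_mb = r(meanInt),
    start_mb = r(placed$start_mb),
    end_mb = r(placed$end_mb),
    cover_size_mb = r(cover),
    refseq_mb = r(placed$refseq_mb),
    coverage_pct = r(coverage))
  ok <- !few
  totCover <- sum(cover[ok])
  totRef <- sum(placed$refseq_mb) + unplacedRefMb
  totals <- list(
    total_markers = sum(perChrom$n_markers) + as.integer(nUnplaced),
    n_unplaced = as.integer(nUnplaced),
    total_cover_mb = r(totCover),
    total_refseq_mb = r(totRef),
    total_coverage_pct = r(100 * totCover / totRef),
    overall_mean_interval_mb = r(totCover / sum(placed$n_markers[ok] - 1)),
    overall_max_interval_mb =
      if (hasMax) r(max(placed$max_interval_mb, na.rm = TRUE)) else NA_real_)
  new("PlatformSummary", perChrom = perChrom, totals = totals,
      decimals = as.integer(decimals))
}

#' Summarise genome coverage of a marker panel
#'
#' Computes, per chromosome, the terminal marker positions, the covered size
#' (last minus first marker, in Mb), the mean adjacent-marker interval
#' (cover / (n - 1)), the maximum interval, and the percentage of the
#' reference chromosome covered; plus panel totals in which every placed
#' chromosome contributes (n - 1) intervals and unplaced markers and
#' reference length enter only the marker total and the coverage
#' denominator. All reported values are rounded half-up to `decimals`.
#'
#' Two inputs are supported: a [CoreSet-class] with marker positions, or a
#' pre-aggregated per-chromosome data.frame (columns `chrom`, `n_markers`,
#' `start_mb`, `end_mb`, `refseq_mb`, optionally `max_interval_mb`; rows
#' with `chrom == "Un"` or NA positions are treated as unplaced and
#' contribute their `n_markers` and `refseq_mb` to the totals).
#'
#' @param x a `CoreSet` or per-chromosome data.frame as above.
#' @param chromSizes for the `CoreSet` method: data.frame with `chrom` and
#'   `size_mb` giving reference chromosome sizes; an optional `"Un"` row
#'   supplies the unplaced reference length (overridden by
#'   `unplacedRefMb`).
#' @param unplacedRefMb reference length (Mb) of unplaced scaffolds added to
#'   the total-coverage denominator.
#' @param unplacedMarkers for the data.frame method: unplaced marker count
#'   when no "Un" row is present.
#' @param decimals decimals for half-up rounding of reported values
#'   (default 1).
#' @param ... unused.
#' @return A [PlatformSummary-class].
#' @examples
#' core <- CoreSet(data.frame(marker_id = c("m1", "m2", "m3"), chrom = "1H",
#'                            pos_bp = c(0, 3e6, 10e6)))
#' summarizePlatform(core, data.frame(chrom = "1H", size_mb = 10))
#' @rdname summarizePlatform
#' @export
setMethod("summarizePlatform", "CoreSet",
  function(x, chromSizes, unplacedRefMb = NULL, decimals = 1, ...) {
    .checkCols(chromSizes, c("chrom", "size_mb"), "chromosome size table")
    m <- coreMarkers(x)
    placedM <- m[m$chrom != "Un" & !is.na(m$pos_bp), , drop = FALSE]
    nUn <- nrow(m) - nrow(placedM)
    if (is.null(unplacedRefMb)) {
      unplacedRefMb <- if ("Un" %in% chromSizes$chrom)
        chromSizes$size_mb[match("Un", chromSizes$chrom)] else 0
    }
    chroms <- unique(placedM$chrom)
    missing <- setdiff(chroms, chromSizes$chrom)
    if (length(missing))
      stop("chromosome(s) absent from chromSizes: ",
           paste(missing, collapse = ", "))
    rows <- lapply(chroms, function(ch) {
      pos <- sort(placedM$pos_bp[placedM$chrom == ch]) / 1e6
      data.frame(chrom = ch, n_markers = length(pos),
                 start_mb = pos[1], end_mb = pos[length(pos)],
                 refseq_mb = chromSizes$size_mb[match(ch, chromSizes$chrom)],
                 max_interval_mb = if (length(pos) >= 2) max(diff(pos))
                                   else NA_real_)
    })
    .platformFromChromTable(do.call(rbind, rows), nUn, unplacedRefMb,
                            decimals)
  })

#' @rdname summarizePlatform
#' @export
setMethod("summarizePlatform", "data.frame",
  function(x, unplacedMarkers = 0, unplacedRefMb = 0, decimals = 1, ...) {
    .checkCols(x, c("chrom", "n_markers", "start_mb", "end_mb", "refseq_mb"),
               "per-chromosome table")
    isUn <- x$chrom == "Un" | is.na(x$start_mb) | is.na(x$end_mb)
    un <- x[isUn, , drop = FALSE]
    nUn <- unplacedMarkers + sum(un$n_markers, na.rm = TRUE)
    unRef <- unplacedRefMb + sum(un$refseq_mb, na.rm = TRUE)
    .platformFromChromTable(x[!isUn, , drop = FALSE], nUn, unRef, decimals)
  })

#' Count markers with secondary polymorphisms
#'
#' Amplicon markers can carry polymorphic sites other than the target SNP;
#' such markers are more informative (they support multi-allelic haplotype
#' analysis). This counts the core-set markers whose
#' `n_extra_polymorphisms` is positive.
#'
#' @param core a [CoreSet-class] whose marker table has a populated
#'   `n_extra_polymorphisms` column.
#' @return list with `count` (integer) and `fraction` (count / panel size).
#' @export
countSecondaryPolymorphic <- function(core) {
  m <- coreMarkers(core)
  .checkCols(m, "n_extra_polymorphisms", "core marker table")
  if (anyNA(m$n_extra_polymorphisms))
    stop("n_extra_polymorphisms contains NA")
  cnt <- sum(m$n_extra_polymorphisms > 0)
  list(count = as.integer(cnt), fraction = cnt / nrow(m))
}
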