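# Fixed physical-distance classes for LD decay (bp, half-open [low, high)):
# 1: <1 Mb, 2: 1-5, 3: 5-10, 4: 10-50, 5: 50-100, 6: 100-200, 7: 200-400,
# 8: >=400 Mb.
.ldClassBreaksBp <- c(0, 1, 5, 10, 50, 100, 200, 400, Inf) * 1e6

#' Covariance-matrix principal component analysis of genotypes
#'
#' PCA of the accessions on mean-imputed, per-site-centered (but not
#' variance-scaled) dosages, i.e. an eigendecomposition of the accession
#' covariance matrix. The proportion of variation explained is each
#' eigenvalue over the trace, so over the full decomposition the
#' percentages sum to 100.
#'
#' @param gm a [GenotypeData-class] with at least 2 accessions and 2 sites.
#' @param k number of components to return scores for (default 3);
#'   truncated with a warning when it exceeds the rank.
#' @return list with `scores` (accessions x k), `explainedPct` (all
#'   components), and `k`.
#' @export
pcaCovariance <- function(gm, k = 3) {
  d <- dosages(gm)
  if (ncol(d) < 2 || nrow(d) < 2)
    stop("need at least 2 accessions and 2 sites")
  siteMeans <- rowMeans(d, na.rm = TRUE)
  if (anyNA(siteMeans)) stop("site(s) with no non-missing calls; filter first")
  X <- t(d)
  idx <- which(is.na(X))
  if (length(idx)) X[idx] <- siteMeans[(idx - 1) %/% nrow(X) + 1]
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  expl <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  if (k > ncol(pc$x)) {
    warning("k exceeds the rank (", ncol(pc$x), "); truncated")
    k <- ncol(pc$x)
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- colnames(d)
  list(scores = scores, explainedPct = expl, k = k)
}

#' Pairwise intra-chromosomal linkage disequilibrium
#'
#' For pairs of sites on the same chromosome, computes `r2`, the squared
#' Pearson correlation of genotype dosages over accessions non-missing at
#' both sites. Pairs with fewer than `minObs` complete observations or zero
#' variance at either site are skipped. When a chromosome has more than
#' `maxPairsPerChrom` pairs, a seeded uniform subsample is taken.
#'
#' @param gm a [GenotypeData-class] (typically after [siteFilter()]).
#' @param maxPairsPerChrom cap on pairs per chromosome (default 5000;
#'   `Inf` for full enumeration).
#' @param minObs minimum complete observations per pair (default 20).
#' @param seed seed for the pair subsample (default 1).
#' @return data.frame with `site1`, `site2`, `chrom`, `distance_bp`, `r2`,
#'   `n_obs`; skipped-pair counts are in `attr(, "skipped")`.
#' @export
ldPairwise <- function(gm, maxPairsPerChrom = 5000, minObs = 20, seed = 1) {
  si <- siteInfo(gm)
  d <- dosages(gm)
  out <- list()
  nSkipped <- 0L
  set.seed(seed)
  for (ch in unique(si$chrom[si$chrom != "Un"])) {
    rows <- which(si$chrom == ch)
    if (length(rows) < 2) next
    X <- t(d[rows, , drop = FALSE])      # accessions x sites
    obs <- !is.na(X)
    nObs <- crossprod(obs)               # complete pairs per site pair
    C <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
    pairs <- which(upper.tri(nObs), arr.ind = TRUE)
    if (nrow(pairs) > maxPairsPerChrom)
      pairs <- pairs[sample.int(nrow(pairs), maxPairsPerChrom), ,
                     drop = FALSE]
    i <- pairs[, 1]; j <- pairs[, 2]
    r2 <- C[pairs]^2
    n <- nObs[pairs]
    ok <- !is.na(r2) & n >= minObs
    nSkipped <- nSkipped + sum(!ok)
    if (!any(ok)) next
    i <- i[ok]; j <- j[ok]
    out[[ch]] <- data.frame(
      site1 = si$marker_id[rows[i]], site2 = si$marker_id[rows[j]],
      chrom = ch,
      distance_bp = abs(si$pos_bp[rows[j]] - si$pos_bp[rows[i]]),
      r2 = r2[ok], n_obs = n[ok])
  }
  res <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
         else data.frame(site1 = character(), site2 = character(),
                         chrom = character(), distance_bp = numeric(),
                         r2 = numeric(), n_obs = numeric())
  attr(res, "skipped") <- nSkipped
  res
}

#' Assign LD records to physical-distance classes
#'
#' Labels each site pair with one of eight fixed distance classes
#' (half-open in bp): 1: under 1 Mb, 2: 1-5 Mb, 3: 5-10 Mb, 4: 10-50 Mb,
#' 5: 50-100 Mb, 6: 100-200 Mb, 7: 200-400 Mb, 8: 400 Mb and above; and
#' summarises `r2` per class.
#'
#' @param records data.frame from [ldPairwise()] (needs `distance_bp`,
#'   `r2`).
#' @return list with `records` (input plus `distance_class`) and `summary`
#'   (per class: `n`, `median_r2`, `q1_r2`, `q3_r2`).
#' @examples
#' r <- data.frame(distance_bp = c(5e5, 5e6), r2 = c(0.9, 0.2))
#' binDistanceClasses(r)$records$distance_class  # 1, 3
#' @export
binDistanceClasses <- function(records) {
  .checkCols(records, c("distance_bp", "r2"), "LD record table")
  if (any(records$distance_bp <= 0))
    stop("distances must be positive")
  cls <- findInterval(records$distance_bp, .ldClassBreaksBp,
                      rightmost.closed = FALSE)
  records$distance_class <- as.integer(cls)
  sp <- split(records$r2, records$distance_class)
  summary <- data.frame(
    distance_class = as.integer(names(sp)),
    n = lengths(sp),
    median_r2 = vapply(sp, median, numeric(1)),
    q1_r2 = vapply(sp, quantile, numeric(1), probs = 0.25, names = FALSE),
    q3_r2 = vapply(sp, quantile, numeric(1), probs = 0.75, names = FALSE))
  rownames(summary) <- NULL
  list(records = records, summary = summary)
}

#' Empirical percentile of an r2 threshold
#'
#' The percentile rank of `threshold` in the distribution of pairwise `r2`
#' values: 100 times the fraction of records with `r2 <= threshold`. Used
#' to justify a minimum-r2 cutoff for declaring significant association
#' between site pairs.
#'
#' @param records data.frame with an `r2` column.
#' @param threshold r2 cutoff (default 0.1).
#' @return numeric percentile in \[0, 100\].
#' @export
ldThresholdPercentile <- function(records, threshold = 0.1) {
  .checkCols(records, "r2", "LD record table")
  if (nrow(records) < 100)
    warning("fewer than 100 LD records; percentile is unstable")
  100 * mean(records$r2 <= threshold)
}

# Piepho-style insert-and-absorb compact letter display from a logical
# significance matrix over groups (TRUE = significantly different).
.letterDisplay <- function(groups, sigPair) {
  sets <- list(groups)
  for (p in seq_len(nrow(sigPair))) {
    a <- sigPair$g1[p]; b <- sigPair$g2[p]
    hit <- which(vapply(sets, function(s) a %in% s && b %in% s, logical(1)))
    for (h in hit) {
      s <- sets[[h]]
      sets[[h]] <- setdiff(s, a)
      sets[[length(sets) + 1L]] <- setdiff(s, b)
    }
    # absorb sets contained in another; dedupe
    keep <- rep(TRUE, length(sets))
    for (i in seq_along(sets)) for (j in seq_along(sets)) {
      if (i != j && keep[i] && keep[j] &&
          all(sets[[i]] %in% sets[[j]]) &&
          (length(sets[[i]]) < length(sets[[j]]) || i > j))
        keep[i] <- FALSE
    }
    sets <- sets[keep]
  }
  # stable order: by first group member
  ord <- order(vapply(sets, function(s) match(s[1], groups), numeric(1)))
  sets <- sets[ord]
  vapply(groups, function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = "")
  }, character(1))
}

#' Compare LD distance classes by ANOVA and Tukey HSD
#'
#' One-way analysis of variance of `r2` on distance class, followed by
#' Tukey honest-significant-difference pairwise comparisons at level
#' `alpha`, summarised as a compact letter display: classes sharing no
#' letter differ significantly. Classes with fewer than 2 records are
#' excluded.
#'
#' @param records data.frame with `r2` and `distance_class` (see
#'   [binDistanceClasses()]).
#' @param alpha significance level (default 0.05).
#' @return data.frame per class: `distance_class`, `n`, `mean_r2`,
#'   `letters`; the Tukey table is in `attr(, "tukey")`.
#' @export
compareDistanceClasses <- function(records, alpha = 0.05) {
  .checkCols(records, c("r2", "distance_class"), "LD record table")
  tab <- table(records$distance_class)
  keep <- names(tab)[tab >= 2]
  if (length(keep) < 2)
    stop("need at least 2 distance classes with at least 2 records")
  rec <- records[records$distance_class %in% keep, , drop = FALSE]
  rec$cls <- factor(rec$distance_class)
  fit <- aov(r2 ~ cls, data = rec)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$cls
  cmp <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  sig <- data.frame(g1 = cmp[, 1], g2 = cmp[, 2])[tk[, "p adj"] < alpha, ,
                                                  drop = FALSE]
  groups <- levels(rec$cls)
  lett <- .letterDisplay(groups, sig)
  out <- data.frame(
    distance_class = as.integer(groups),
    n = as.integer(table(rec$cls)),
    mean_r2 = as.numeric(tapply(rec$r2, rec$cls, mean)),
    letters = unname(lett))
  attr(out, "tukey") <- tk
  out
}
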