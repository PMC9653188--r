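#' Scale phenotypes within breeding-station by harvest-year groups
#'
#' Breeding stations differ in growth conditions, evaluation procedures and
#' equipment, so raw trait values shift in location and scale between
#' station-year combinations. Within each (station, year) group, per trait,
#' this subtracts the group mean and divides by the group sample standard
#' deviation (n - 1 denominator), making values comparable across groups.
#' Groups with fewer than 2 records or identical values are centered only,
#' with a warning.
#'
#' @param pheno data.frame in long format with columns `accession`,
#'   `station`, `year`, `trait`, `value`.
#' @param traits optional character vector restricting the traits; an
#'   absent trait is an error.
#' @return `pheno` with an added `scaled` column.
#' @examples
#' p <- data.frame(accession = c("a", "b", "c"), station = "NICS",
#'                 year = 2018, trait = "TGW", value = c(1, 2, 3))
#' scaleByGroup(p)$scaled  # -1 0 1
#' @export
scaleByGroup <- function(pheno, traits = NULL) {
  .checkCols(pheno, c("accession", "station", "year", "trait", "value"),
             "phenotype table")
  if (any(is.na(pheno$station)) || any(is.na(pheno$year)))
    stop("station and year must be non-missing")
  if (!is.null(traits)) {
    absent <- setdiff(traits, unique(pheno$trait))
    if (length(absent))
      stop("trait(s) absent from phenotype table: ",
           paste(absent, collapse = ", "))
    pheno <- pheno[pheno$trait %in% traits, , drop = FALSE]
  }
  key <- interaction(pheno$station, pheno$year, pheno$trait, drop = TRUE)
  scaled <- rep(NA_real_, nrow(pheno))
  degenerate <- character()
  for (g in levels(key)) {
    idx <- which(key == g)
    v <- pheno$value[idx]
    s <- sd(v)
    if (length(v) >= 2 && !is.na(s) && s > 0) {
      scaled[idx] <- (v - mean(v)) / s
    } else {
      scaled[idx] <- v - mean(v)
      degenerate <- c(degenerate, g)
    }
  }
  if (length(degenerate))
    warning("group(s) centered only (fewer than 2 records or constant): ",
            paste(head(degenerate, 5), collapse = ", "),
            if (length(degenerate) > 5) " ..." else "")
  pheno$scaled <- scaled
  pheno
}

#' Fit a ridge-regression BLUP model
#'
#' Fits `y = 1 mu + M u + e` with i.i.d. normal marker effects
#' (`u ~ N(0, I sigma2u)`, `e ~ N(0, I sigma2e)`). Marker columns are
#' centered by their training means (missing dosages imputed by the same
#' means). The variance ratio `lambda = sigma2e / sigma2u` is estimated by
#' restricted maximum likelihood profiled on the eigendecomposition of the
#' marker cross-product `M M'`: the restricted log-likelihood is evaluated
#' on a 101-point grid of log10(lambda) over \[-5, 5\] and refined by
#' Brent's method around the grid optimum. Effects are then
#' `u = M' (M M' + lambda I)^-1 (y - mu)` with `mu` the generalized
#' least-squares intercept (for column-centered `M`, `mu` equals the
#' training mean of `y`, and `u` equals the primal ridge solution
#' `(M'M + lambda I)^-1 M' (y - mean(y))`).
#'
#' @param M numeric matrix, training accessions x markers, dosage-coded
#'   (NA allowed).
#' @param y numeric phenotype vector, one value per row of `M`.
#' @param lambda optional fixed variance ratio; when supplied REML is
#'   skipped.
#' @param bounds log10(lambda) search interval (default `c(-5, 5)`,
#'   covering heritabilities from about 0.001 to 0.999 for standardized
#'   phenotypes).
#' @param nGrid grid size for the profile search (default 101).
#' @return An [RRBlupModel-class]. When `y` has zero variance the model
#'   degenerates to the intercept with zero effects (flagged in the
#'   object).
#' @export
fitRRBlup <- function(M, y, lambda = NULL, bounds = c(-5, 5), nGrid = 101L) {
  M <- as.matrix(M)
  if (length(y) != nrow(M)) stop("length(y) must equal nrow(M)")
  if (anyNA(y)) stop("y must not contain NA")
  n <- nrow(M)
  if (n < 2) stop("need at least 2 training accessions")
  siteIds <- colnames(M)
  if (is.null(siteIds)) siteIds <- sprintf("site%d", seq_len(ncol(M)))
  siteMeans <- colMeans(M, na.rm = TRUE)
  siteMeans[is.nan(siteMeans)] <- 0
  Z <- sweep(M, 2, siteMeans)
  Z[is.na(Z)] <- 0
  K <- tcrossprod(Z)
  meanDiagK <- mean(diag(K))
  if (sd(y) == 0 || meanDiagK == 0) {
    return(new("RRBlupModel", mu = mean(y),
               effects = rep(0, ncol(M)), sigma2u = 0,
               sigma2e = max(var(y), 0), lambda = 1,
               siteIds = siteIds, siteMeans = siteMeans,
               meanDiagK = meanDiagK, zeroVariance = TRUE))
  }
  eig <- eigen(K, symmetric = TRUE)
  theta <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))
  p <- 1L
  remlNegLL <- function(log10lam) {
    lam <- 10^log10lam
    dd <- theta + lam
    xhx <- sum(xt^2 / dd)
    beta <- sum(xt * yt / dd) / xhx
    rss <- sum((yt - xt * beta)^2 / dd)
    s2u <- rss / (n - p)
    0.5 * ((n - p) * log(s2u) + sum(log(dd)) + log(xhx))
  }
  if (is.null(lambda)) {
    grid <- seq(bounds[1], bounds[2], length.out = nGrid)
    vals <- vapply(grid, remlNegLL, numeric(1))
    if (any(!is.finite(vals)))
      stop("non-finite restricted-likelihood surface")
    i <- which.min(vals)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(nGrid, i + 1L)]
    opt <- optimize(remlNegLL, c(lo, hi), tol = 1e-8)
    lambda <- 10^opt$minimum
  } else if (lambda <= 0) stop("lambda must be positive")
  dd <- theta + lambda
  xhx <- sum(xt^2 / dd)
  mu <- sum(xt * yt / dd) / xhx
  resid <- yt - xt * mu
  s2u <- sum(resid^2 / dd) / (n - p)
  s2e <- lambda * s2u
  u <- drop(crossprod(Z, U %*% (resid / dd)))
  new("RRBlupModel", mu = mu, effects = unname(u), sigma2u = s2u,
      sigma2e = s2e, lambda = lambda, siteIds = siteIds,
      siteMeans = siteMeans, meanDiagK = meanDiagK, zeroVariance = FALSE)
}

#' Predict trait values from a fitted RR-BLUP model
#'
#' Applies the model to new accessions: test dosages are centered with the
#' training site means (missing values imputed likewise) and
#' `yhat = mu + M_test u`. Test sites must match the training sites; a
#' differing column order is realigned by site id, unknown or absent sites
#' are an error.
#'
#' @param object an [RRBlupModel-class].
#' @param newdata numeric matrix, test accessions x markers, or a
#'   [GenotypeData-class] (transposed internally).
#' @param ... unused.
#' @return numeric vector of predicted values.
#' @export
setMethod("predict", "RRBlupModel", function(object, newdata, ...) {
  if (is(newdata, "GenotypeData")) newdata <- t(dosages(newdata))
  newdata <- as.matrix(newdata)
  ids <- colnames(newdata)
  if (!is.null(ids) && !identical(ids, object@siteIds)) {
    bad <- c(setdiff(ids, object@siteIds), setdiff(object@siteIds, ids))
    if (length(bad))
      stop("test sites do not match training sites: ",
           paste(head(bad, 10), collapse = ", "),
           if (length(bad) > 10) " ..." else "")
    newdata <- newdata[, object@siteIds, drop = FALSE]
  }
  if (ncol(newdata) != length(object@effects))
    stop("test matrix has ", ncol(newdata), " sites; model has ",
         length(object@effects))
  Z <- sweep(newdata, 2, object@siteMeans)
  Z[is.na(Z)] <- 0
  drop(object@mu + Z %*% object@effects)
})

# Internal: per-accession trait vector and aligned dosage matrix.
.traitMatrix <- function(gm, pheno, trait, useScaled = TRUE) {
  sub <- pheno[pheno$trait == trait, , drop = FALSE]
  if (nrow(sub) == 0) stop("trait absent from phenotype table: ", trait)
  if (anyDuplicated(sub$accession))
    stop("multiple records per accession for trait ", trait)
  valueCol <- if (useScaled && "scaled" %in% names(sub)) "scaled" else "value"
  sub <- sub[!is.na(sub[[valueCol]]), , drop = FALSE]
  acc <- intersect(colnames(dosages(gm)), sub$accession)
  if (length(acc) < 2)
    stop("fewer than 2 genotyped, phenotyped accessions for trait ", trait)
  sub <- sub[match(acc, sub$accession), , drop = FALSE]
  list(M = t(dosages(gm)[, acc, drop = FALSE]),
       y = sub[[valueCol]], meta = sub)
}

#' Cross-validated genomic prediction accuracy
#'
#' Repeatedly holds out a random fraction `1/k` of the phenotyped
#' accessions as a test set, trains an RR-BLUP model on the remainder, and
#' correlates predicted with observed values on the hold-out. The default
#' scheme draws one random fifth per repetition (repeated hold-out);
#' `scheme = "kfold"` instead rotates through a full k-fold partition per
#' repetition and averages the per-fold correlations. Repetitions whose
#' hold-out has constant observed values are redrawn (logged in the
#' result).
#'
#' @param gm a [GenotypeData-class].
#' @param pheno phenotype table, typically from [scaleByGroup()]; the
#'   `scaled` column is used when present.
#' @param trait trait name.
#' @param k hold-out fraction denominator (default 5).
#' @param reps number of repetitions (default 100).
#' @param seed RNG seed; results are bit-reproducible given
#'   (seed, reps, k).
#' @param scheme `"holdout"` (default) or `"kfold"`.
#' @param accuracy `"pearson"` (default) or `"spearman"` correlation.
#' @return list with `trait`, `scheme`, `k`, `nReps`, `correlations`
#'   (per repetition), `cvMean`, `cvSd`, `n` (accessions used), and
#'   `redraws`.
#' @export
crossValidate <- function(gm, pheno, trait, k = 5, reps = 100, seed = 1,
                          scheme = c("holdout", "kfold"),
                          accuracy = c("pearson", "spearman")) {
  scheme <- match.arg(scheme)
  accuracy <- match.arg(accuracy)
  tm <- .traitMatrix(gm, pheno, trait)
  n <- length(tm$y)
  if (n < 2 * k)
    stop("too few phenotyped accessions (", n, ") for k = ", k)
  set.seed(seed)
  cors <- numeric(reps)
  redraws <- 0L
  for (r in seq_len(reps)) {
    if (scheme == "holdout") {
      for (try in 1:100) {
        test <- sample.int(n, max(2L, floor(n / k)))
        if (sd(tm$y[test]) > 0 && sd(tm$y[-test]) > 0) break
        redraws <- redraws + 1L
      }
      fit <- fitRRBlup(tm$M[-test, , drop = FALSE], tm$y[-test])
      pred <- predict(fit, tm$M[test, , drop = FALSE])
      cors[r] <- cor(pred, tm$y[test], method = accuracy)
    } else {
      folds <- sample(rep_len(seq_len(k), n))
      fc <- vapply(seq_len(k), function(f) {
        test <- which(folds == f)
        fit <- fitRRBlup(tm$M[-test, , drop = FALSE], tm$y[-test])
        cor(predict(fit, tm$M[test, , drop = FALSE]), tm$y[test],
            method = accuracy)
      }, numeric(1))
      cors[r] <- mean(fc)
    }
  }
  list(trait = trait, scheme = scheme, k = k, nReps = reps,
       correlations = cors, cvMean = mean(cors), cvSd = sd(cors), n = n,
       redraws = redraws)
}

#' Cross-year genomic prediction
#'
#' Trains an RR-BLUP model on the accessions of one harvest year and
#' predicts those of another; accuracy is the correlation between predicted
#' and observed values in the test year.
#'
#' @inheritParams crossValidate
#' @param trainYear,testYear harvest years; both must be present for the
#'   trait.
#' @return list with `trait`, `trainYear`, `testYear`, `correlation`,
#'   `nTrain`, `nTest`.
#' @export
crossYearPredict <- function(gm, pheno, trait, trainYear, testYear,
                             accuracy = c("pearson", "spearman")) {
  accuracy <- match.arg(accuracy)
  tm <- .traitMatrix(gm, pheno, trait)
  yr <- tm$meta$year
  trainIdx <- which(yr == trainYear)
  testIdx <- which(yr == testYear)
  if (length(trainIdx) == 0) stop("no accessions for train year ", trainYear)
  if (length(testIdx) == 0) stop("no accessions for test year ", testYear)
  fit <- fitRRBlup(tm$M[trainIdx, , drop = FALSE], tm$y[trainIdx])
  pred <- predict(fit, tm$M[testIdx, , drop = FALSE])
  list(trait = trait, trainYear = trainYear, testYear = testYear,
       correlation = cor(pred, tm$y[testIdx], method = accuracy),
       nTrain = length(trainIdx), nTest = length(testIdx))
}

#' Assemble a prediction-accuracy report
#'
#' Combines cross-validation and cross-year results into one row per trait:
#' CV mean and SD over repetitions, both cross-year directions, and their
#' arithmetic mean.
#'
#' @param cvResults list of [crossValidate()] results.
#' @param crossYearResults optional list of [crossYearPredict()] results
#'   (any number of directions per trait).
#' @return data.frame with columns `trait`, `cv_mean`, `cv_sd`, `n_reps`,
#'   one `cy_<train>_<test>` column per direction, and `cy_mean`.
#' @export
predictionReport <- function(cvResults, crossYearResults = NULL) {
  rows <- lapply(cvResults, function(cv) {
    data.frame(trait = cv$trait, cv_mean = cv$cvMean, cv_sd = cv$cvSd,
               n_reps = cv$nReps)
  })
  out <- do.call(rbind, rows)
  if (!is.null(crossYearResults)) {
    for (cy in crossYearResults) {
      col <- sprintf("cy_%s_%s", cy$trainYear, cy$testYear)
      if (!col %in% names(out)) out[[col]] <- NA_real_
      out[[col]][out$trait == cy$trait] <- cy$correlation
    }
    cyCols <- grep("^cy_", names(out), value = TRUE)
    out$cy_mean <- rowMeans(out[, cyCols, drop = FALSE], na.rm = TRUE)
  }
  rownames(out) <- NULL
  out
}
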