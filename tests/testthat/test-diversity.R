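test_that("covariance PCA has the expected degenerate behaviour", {
  # duplicated accessions collapse to a single point
  base <- rbind(c(0, 0, 2, 2, 0, 2), c(2, 0, 0, 2, 2, 0),
                c(0, 2, 2, 0, 0, 2), c(2, 2, 0, 0, 2, 0))
  d <- base[, c(1, 1, 2, 2, 3, 3)]
  colnames(d) <- sprintf("a%d", 1:6)
  pca <- pcaCovariance(makeGD(d), k = 2)
  expect_lt(max(abs(pca$scores["a1", ] - pca$scores["a2", ])), 1e-10)
  # rank-1 structure: PC1 explains everything
  v <- c(0, 1, 2, 1, 0)
  d1 <- rbind(v, v, 2 - v, v)
  colnames(d1) <- sprintf("b%d", 1:5)
  pca1 <- pcaCovariance(makeGD(d1), k = 1)
  expect_gt(pca1$explainedPct[1], 99.999)
  # explained percentages sum to 100 over the full decomposition
  gd <- simulatePopulation(smallPopConfig(seed = 2, nAccessions = 60,
                                          nMarkers = 80))$gd
  expect_equal(sum(pcaCovariance(gd, k = 2)$explainedPct), 100)
})

test_that("PCA scores are invariant to shifting a site's dosages", {
  d <- rbind(c(0, 1, 0, 1, 0, 1), c(0, 0, 2, 2, 0, 2),
             c(1, 0, 1, 0, 1, 0))
  colnames(d) <- sprintf("a%d", 1:6)
  d2 <- d
  d2[1, ] <- d2[1, ] + 1   # still valid dosages
  s1 <- pcaCovariance(makeGD(d), k = 2)$scores
  s2 <- pcaCovariance(makeGD(d2), k = 2)$scores
  # scores equal up to component sign
  for (j in 1:2)
    expect_lt(min(max(abs(s1[, j] - s2[, j])),
                  max(abs(s1[, j] + s2[, j]))), 1e-10)
})

test_that("planted station structure is recovered from PC scores", {
  sim <- simulatePopulation(smallPopConfig(seed = 4))
  pca <- pcaCovariance(sim$gd, k = 2)
  km <- kmeans(pca$scores, centers = 3, nstart = 25)
  expect_gte(permAgreement(km$cluster, sim$truth$station), 0.9)
})

test_that("populations without divergence show no station clustering", {
  # a wide founder pool removes the founder-sampling bottleneck, so with
  # fst = 0 stations are effectively exchangeable
  sim <- simulatePopulation(smallPopConfig(seed = 6, fst = 0,
                                           founderCount = 40))
  pca <- pcaCovariance(sim$gd, k = 2)
  km <- kmeans(pca$scores, centers = 3, nstart = 25)
  agree0 <- permAgreement(km$cluster, sim$truth$station)
  expect_lt(agree0, 0.6)
  simF <- simulatePopulation(smallPopConfig(seed = 6, fst = 0.1,
                                            founderCount = 40))
  pcaF <- pcaCovariance(simF$gd, k = 2)
  kmF <- kmeans(pcaF$scores, centers = 3, nstart = 25)
  expect_gt(permAgreement(kmF$cluster, simF$truth$station), agree0)
})

test_that("r2 matches direct correlation and is label-symmetric", {
  x <- c(0, 0, 2, 2, 1, 0, 2, 1)
  y <- c(2, 2, 0, 0, 1, 2, 0, 2)
  d <- rbind(x, x, y)
  colnames(d) <- sprintf("a%d", 1:8)
  gd <- makeGD(d, pos = c(1e6, 2e6, 3e6))
  ld <- ldPairwise(gd, minObs = 5)
  dup <- ld[ld$site1 == "m001" & ld$site2 == "m002", ]
  expect_equal(dup$r2, 1)
  # brute-force correlation from raw sums for the (x, y) pair
  n <- length(x)
  handR <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  pair <- ld[ld$site1 == "m001" & ld$site2 == "m003", ]
  expect_equal(pair$r2, handR^2, tolerance = 1e-12)
  # allele-label swap at one site leaves r2 unchanged
  d2 <- d; d2[3, ] <- 2 - d2[3, ]
  ld2 <- ldPairwise(makeGD(d2, pos = c(1e6, 2e6, 3e6)), minObs = 5)
  expect_equal(ld2$r2, ld$r2)
})

test_that("pairs below the observation floor are skipped", {
  d <- rbind(c(0, 2, NA, NA, NA, NA), c(0, 2, 0, 2, 0, 2))
  colnames(d) <- sprintf("a%d", 1:6)
  ld <- ldPairwise(makeGD(d), minObs = 5)
  expect_equal(nrow(ld), 0)
  expect_gte(attr(ld, "skipped"), 1)
})

test_that("distance classes use half-open megabase boundaries", {
  rec <- data.frame(distance_bp = c(0.5e6, 1e6, 5e6, 9.99e6, 10e6,
                                    399.9e6, 400e6, 1e9),
                    r2 = 0.2)
  cls <- binDistanceClasses(rec)$records$distance_class
  expect_identical(cls, c(1L, 2L, 3L, 3L, 4L, 7L, 8L, 8L))
  # exactly one class each; counts add up
  s <- binDistanceClasses(rec)$summary
  expect_identical(sum(s$n), nrow(rec))
})

test_that("class medians decrease under a generated exponential decay", {
  set.seed(99)
  d <- 10^runif(4000, 4.5, 8.8)         # 30 kb .. 630 Mb
  r2 <- pmin(1, pmax(0, exp(-d / 4e7) + rnorm(4000, 0, 0.02)))
  b <- binDistanceClasses(data.frame(distance_bp = d, r2 = r2))
  med <- b$summary$median_r2[order(b$summary$distance_class)]
  expect_true(all(diff(med) < 0))
})

test_that("threshold percentile matches hand counts and a known CDF", {
  rec <- data.frame(r2 = c(rep(0.05, 9), 0.5))
  expect_warning(p <- ldThresholdPercentile(rec, 0.1), "fewer than 100")
  expect_equal(p, 90)
  expect_equal(suppressWarnings(
    ldThresholdPercentile(data.frame(r2 = rep(0.01, 50)), 0.1)), 100)
  # mixture with analytic CDF at 0.1 equal to 0.5 exactly
  set.seed(5)
  n <- 20000
  grp <- runif(n) < 0.5
  r2 <- ifelse(grp, runif(n, 0, 0.08), runif(n, 0.12, 1))
  p2 <- ldThresholdPercentile(data.frame(r2 = r2), 0.1)
  expect_lt(abs(p2 - 50), 3 * 50 / sqrt(n) * 2)
})

test_that("Tukey letter display separates shifted classes only", {
  set.seed(11)
  same <- data.frame(r2 = rnorm(400, 0.2, 0.05),
                     distance_class = rep(1:2, each = 200))
  cmpSame <- compareDistanceClasses(same)
  shared <- any(vapply(strsplit(cmpSame$letters[1], "")[[1]],
                       grepl, logical(1), x = cmpSame$letters[2],
                       fixed = TRUE))
  expect_true(shared)
  off <- data.frame(r2 = c(rnorm(200, 0.2, 0.05), rnorm(200, 0.45, 0.05)),
                    distance_class = rep(1:2, each = 200))
  cmpOff <- compareDistanceClasses(off)
  expect_false(any(strsplit(cmpOff$letters[1], "")[[1]] %in%
                     strsplit(cmpOff$letters[2], "")[[1]]))
  # three classes, one planted equal pair: the equal pair shares a letter
  tri <- data.frame(
    r2 = c(rnorm(150, 0.2, 0.05), rnorm(150, 0.2, 0.05),
           rnorm(150, 0.6, 0.05)),
    distance_class = rep(1:3, each = 150))
  cmpTri <- compareDistanceClasses(tri)
  l <- strsplit(cmpTri$letters, "")
  expect_true(length(intersect(l[[1]], l[[2]])) > 0)
  expect_true(length(intersect(l[[1]], l[[3]])) == 0)
})

test_that("letter sharing has near-nominal type-I behaviour", {
  set.seed(42)
  sharedCount <- 0
  reps <- 120
  for (i in seq_len(reps)) {
    x <- data.frame(r2 = rnorm(160, 0.3, 0.1),
                    distance_class = rep(1:2, each = 80))
    cmp <- compareDistanceClasses(x)
    l <- strsplit(cmp$letters, "")
    if (length(intersect(l[[1]], l[[2]])) > 0)
      sharedCount <- sharedCount + 1
  }
  expect_gte(sharedCount / reps, 0.9)
})
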