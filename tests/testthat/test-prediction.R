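test_that("group scaling standardises within station-year groups", {
  p <- data.frame(accession = c("a", "b", "c"), station = "S1",
                  year = 2018, trait = "TGW", value = c(1, 2, 3))
  expect_equal(scaleByGroup(p)$scaled, c(-1, 0, 1))
  p2 <- rbind(p, data.frame(accession = c("d", "e", "f"), station = "S2",
                            year = 2019, trait = "TGW",
                            value = c(100, 150, 200)))
  s <- scaleByGroup(p2)
  for (g in split(s, paste(s$station, s$year))) {
    expect_equal(mean(g$scaled), 0)
    expect_equal(sd(g$scaled), 1)
  }
  expect_error(scaleByGroup(p, traits = "GPC"), "absent")
  pDeg <- data.frame(accession = c("a", "b"), station = "S1", year = 2018,
                     trait = "T", value = c(5, 5))
  expect_warning(sDeg <- scaleByGroup(pDeg), "centered only")
  expect_equal(sDeg$scaled, c(0, 0))
})

test_that("group scaling makes station-shifted distributions comparable", {
  cfg <- smallPopConfig(seed = 12, traits = list(
    list(name = "T", nQtl = 40, h2 = 0.5, stationEffectSd = 2,
         yearEffectSd = 0.5, scaleSdLog = 0.15)))
  sim <- simulatePopulation(cfg)
  ph <- simulatePhenotypes(sim$truth, sim$gd, cfg)
  raw <- ph$pheno
  betweenVar <- var(tapply(raw$value, raw$station, mean))
  withinVar <- mean(tapply(raw$value, paste(raw$station, raw$year), var))
  expect_gt(betweenVar, withinVar)  # stations shift location strongly
  s <- scaleByGroup(raw)
  groupMeans <- tapply(s$scaled, paste(s$station, s$year), mean)
  expect_lt(max(abs(groupMeans)), 1e-10)
})

test_that("the dual-form solution equals the explicit ridge oracle", {
  set.seed(101)
  for (lambda in c(0.5, 3, 25)) {
    M <- matrix(sample(0:2, 20 * 50, replace = TRUE), 20, 50)
    y <- rnorm(20)
    fit <- fitRRBlup(M, y, lambda = lambda)
    Z <- scale(M, center = TRUE, scale = FALSE)
    uOracle <- solve(crossprod(Z) + lambda * diag(50),
                     crossprod(Z, y - mean(y)))
    expect_equal(fit@mu, mean(y), tolerance = 1e-10)
    expect_lt(max(abs(unname(markerEffects(fit)) - drop(uOracle))) /
                max(abs(uOracle)), 1e-8)
  }
})

test_that("degenerate and limiting fits behave as ridge theory demands", {
  M <- matrix(sample(0:2, 30 * 40, replace = TRUE), 30, 40)
  # constant phenotype: intercept-only model
  fitC <- fitRRBlup(M, rep(3, 30))
  expect_true(fitC@zeroVariance)
  expect_equal(unname(predict(fitC, M)), rep(3, 30))
  expect_equal(fitC@sigma2u, 0)
  # enormous lambda shrinks every prediction to the intercept
  y <- rnorm(30)
  fitL <- fitRRBlup(M, y, lambda = 1e9)
  expect_lt(max(abs(predict(fitL, M) - fitL@mu)), 1e-4)
  # predicting the training rows returns the fitted values
  fit <- fitRRBlup(M, y)
  Z <- sweep(M, 2, fit@siteMeans)
  expect_equal(unname(predict(fit, M)),
               drop(fit@mu + Z %*% fit@effects))
})

test_that("predictions are invariant to affine dosage recoding", {
  set.seed(7)
  M <- matrix(sample(0:2, 40 * 60, replace = TRUE), 40, 60)
  y <- rnorm(40)
  Mtest <- matrix(sample(0:2, 10 * 60, replace = TRUE), 10, 60)
  lam <- 4
  p1 <- predict(fitRRBlup(M, y, lambda = lam), Mtest)
  p2 <- predict(fitRRBlup(M / 2, y, lambda = lam / 4), Mtest / 2)
  expect_equal(p1, p2, tolerance = 1e-10)
  # REML route: correlations agree to optimizer resolution
  pr1 <- predict(fitRRBlup(M, y), Mtest)
  pr2 <- predict(fitRRBlup(M / 2, y), Mtest / 2)
  expect_equal(cor(pr1, pr2), 1, tolerance = 1e-6)
})

test_that("site mismatches at prediction time are reported", {
  M <- matrix(sample(0:2, 20 * 10, replace = TRUE), 20, 10,
              dimnames = list(NULL, sprintf("s%d", 1:10)))
  fit <- fitRRBlup(M, rnorm(20))
  bad <- M[, 1:9]
  expect_error(predict(fit, bad), "s10")
  # reordered columns are realigned, not refused
  expect_equal(predict(fit, M[, 10:1]), predict(fit, M))
})

test_that("REML recovers simulated heritability", {
  h2hat <- vapply(1:4, function(s) {
    cfg <- smallPopConfig(seed = 100 + s, nAccessions = 200,
                          nMarkers = 300, traits = plainTrait(0.5))
    sim <- simulatePopulation(cfg)
    ph <- simulatePhenotypes(sim$truth, sim$gd, cfg)
    y <- alignedY(sim$gd, ph$pheno)
    heritability(fitRRBlup(t(dosages(sim$gd)), y))
  }, numeric(1))
  expect_lt(abs(mean(h2hat) - 0.5), 0.1)
})

test_that("cross-validation tracks heritability and reproduces bit-for-bit", {
  cfg <- smallPopConfig(seed = 55, nAccessions = 150, nMarkers = 200,
                        traits = list(
    list(name = "null", nQtl = 40, h2 = 0, stationEffectSd = 0,
         yearEffectSd = 0, scaleSdLog = 0),
    list(name = "mid", nQtl = 40, h2 = 0.5, stationEffectSd = 0,
         yearEffectSd = 0, scaleSdLog = 0),
    list(name = "full", nQtl = 40, h2 = 1, stationEffectSd = 0,
         yearEffectSd = 0, scaleSdLog = 0)))
  sim <- simulatePopulation(cfg)
  ph <- simulatePhenotypes(sim$truth, sim$gd, cfg)
  pheno <- scaleByGroup(ph$pheno)
  cvNull <- crossValidate(sim$gd, pheno, "null", reps = 20, seed = 3)
  cvMid <- crossValidate(sim$gd, pheno, "mid", reps = 20, seed = 3)
  cvFull <- crossValidate(sim$gd, pheno, "full", reps = 20, seed = 3)
  expect_lt(abs(cvNull$cvMean), 0.15)
  expect_gt(cvFull$cvMean, 0.9)
  expect_true(cvNull$cvMean < cvMid$cvMean &&
                cvMid$cvMean < cvFull$cvMean)
  # bit-for-bit reproducibility under a fixed seed
  again <- crossValidate(sim$gd, pheno, "mid", reps = 20, seed = 3)
  expect_identical(cvMid$correlations, again$correlations)
  # rotating k-fold scheme runs and lands in the same region
  kf <- crossValidate(sim$gd, pheno, "mid", reps = 3, seed = 3,
                      scheme = "kfold")
  expect_lt(abs(kf$cvMean - cvMid$cvMean), 0.2)
})

test_that("cross-year prediction works and degrades with year noise", {
  cfg <- smallPopConfig(seed = 77, nAccessions = 200, nMarkers = 200,
                        traits = plainTrait(1, nQtl = 40))
  sim <- simulatePopulation(cfg)
  ph <- simulatePhenotypes(sim$truth, sim$gd, cfg)
  pheno <- scaleByGroup(ph$pheno)
  fwd <- crossYearPredict(sim$gd, pheno, "T", 2018, 2019)
  bwd <- crossYearPredict(sim$gd, pheno, "T", 2019, 2018)
  expect_gt(fwd$correlation, 0.9)   # noiseless, shared genetics
  expect_gt(bwd$correlation, 0.9)
  expect_error(crossYearPredict(sim$gd, pheno, "T", 2018, 2031), "2031")
  rep <- predictionReport(
    list(crossValidate(sim$gd, pheno, "T", reps = 5, seed = 1)),
    list(fwd, bwd))
  expect_equal(rep$cy_mean, mean(c(fwd$correlation, bwd$correlation)))
  expect_named(rep, c("trait", "cv_mean", "cv_sd", "n_reps",
                      "cy_2018_2019", "cy_2019_2018", "cy_mean"))
})
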