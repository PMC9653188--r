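writeTestVcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "s1", "s2", "s3"),
                     collapse = "\t"),
               lines), path)
  path
}

test_that("VCF genotypes convert to dosages; multi-allelic records drop", {
  vcf <- writeTestVcf(c(
    "c1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "c1\t200\tv2\tA\tG\t.\tPASS\t.\tGT\t0|0\t1|0\t./.",
    "c1\t300\tv3\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2"))
  expect_warning(gd <- loadGenotypes(vcf), "multi-allelic")
  d <- dosages(gd)
  expect_equal(nrow(d), 2)
  expect_equal(unname(d["v1", ]), c(0, 1, 2))
  expect_equal(unname(d["v2", ]), c(0, 1, NA))
  expect_identical(metadata(gd)$skipped_multiallelic, 1L)
  expect_equal(siteInfo(gd)$pos_bp, c(100L, 200L))
})

test_that("simulated data round-trips through the VCF fixture", {
  cfg <- smallPopConfig(seed = 31, nAccessions = 40, nMarkers = 60)
  sim <- simulatePopulation(cfg)
  ph <- simulatePhenotypes(sim$truth, sim$gd, cfg)
  dir <- tempfile("fixture")
  writeFixture(sim$gd, ph$pheno, sim$truth$catalog, dir, truth = ph$truth)
  fx <- loadFixture(dir)
  expect_equal(unname(dosages(fx$gd)), unname(dosages(sim$gd)))
  expect_equal(siteInfo(fx$gd)$pos_bp, siteInfo(sim$gd)$pos_bp)
  expect_equal(accessionInfo(fx$gd)$station, accessionInfo(sim$gd)$station)
  expect_equal(fx$pheno$value, ph$pheno$value, tolerance = 1e-12)
  expect_equal(fx$truth$traits$TGW$realizedH2,
               ph$truth$traits$TGW$realizedH2, tolerance = 1e-9)
})

test_that("site statistics follow allele counting with missing exclusion", {
  gd <- makeGD(rbind(c(0, 0, 2, 2),
                     c(0, 0, 0, 2),
                     c(0, 1, 2, NA)))
  st <- siteStats(gd)
  expect_equal(st$maf, c(0.5, 0.25, 0.5))
  expect_equal(st$missing_rate, c(0, 0, 0.25))
  expect_equal(st$het_rate, c(0, 0, 1 / 3))
})

test_that("MAF is invariant under swapping ref/alt labels", {
  d <- rbind(c(0, 1, 2, 2, 0), c(2, 2, 2, 0, NA))
  st1 <- siteStats(makeGD(d))
  st2 <- siteStats(makeGD(2 - d))
  expect_equal(st1$maf, st2$maf)
  expect_equal(st1$het_rate, st2$het_rate)
})

test_that("site filter removes by OR with strict thresholds", {
  # 10 accessions: site A 60% missing, site B 30% het, site C exactly at
  # both thresholds, site D clean
  A <- c(rep(NA, 6), 0, 0, 2, 2)
  B <- c(rep(1, 3), rep(0, 7))
  C <- c(rep(NA, 5), 1, 0, 0, 2, 2)   # 50% missing, 20% het
  D <- c(rep(0, 5), rep(2, 5))
  gd <- makeGD(rbind(A, B, C, D))
  out <- siteFilter(gd, maxMissing = 0.5, maxHet = 0.2)
  kept <- siteInfo(out)$marker_id
  expect_length(kept, 2)            # C and D survive
  rep <- metadata(out)$siteFilter$removed
  expect_setequal(rep$reason, c("missing", "het"))
  # AND reading keeps everything here (no site fails both)
  outAnd <- siteFilter(gd, combine = "and")
  expect_equal(nrow(dosages(outAnd)), 4)
})

test_that("lowering either threshold removes a superset of sites", {
  cfg <- smallPopConfig(seed = 8, missingRate = 0.25)
  gd <- simulatePopulation(cfg)$gd
  loose <- siteFilter(gd, maxMissing = 0.3, maxHet = 0.5)
  tight <- siteFilter(gd, maxMissing = 0.2, maxHet = 0.5)
  expect_true(all(siteInfo(tight)$marker_id %in%
                    siteInfo(loose)$marker_id))
  removedLoose <- metadata(loose)$siteFilter$removed$marker_id
  removedTight <- metadata(tight)$siteFilter$removed$marker_id
  expect_true(all(removedLoose %in% removedTight))
})

test_that("filtering then stats equals stats restricted to survivors", {
  gd <- simulatePopulation(smallPopConfig(seed = 9,
                                          missingRate = 0.1))$gd
  filt <- siteFilter(gd, maxMissing = 0.08)
  stAll <- siteStats(gd)
  stFilt <- siteStats(filt)
  sub <- stAll[match(stFilt$marker_id, stAll$marker_id), ]
  expect_equal(stFilt$maf, sub$maf)
  expect_equal(stFilt$het_rate, sub$het_rate)
})

test_that("removing every site is an error advising threshold review", {
  gd <- makeGD(rbind(c(NA, NA, NA, 0), c(NA, NA, 0, NA)))
  expect_error(suppressWarnings(siteFilter(gd, maxMissing = 0.5)),
               "threshold")
})

test_that("LOESS profile recovers constant and linear MAF patterns", {
  n <- 60
  # constant: every site has the same dosage composition
  rowsConst <- t(replicate(40, c(rep(0, 45), rep(2, 15))))
  gdConst <- makeGD(rowsConst, pos = seq(1, 40) * 2e6)
  prof <- mafProfile(gdConst, span = 0.5, gridPoints = 50)
  expect_true(all(abs(prof$curve$fit - 0.25) < 1e-6))
  # linear gradient in position: compare with ordinary least squares
  target <- seq(0.05, 0.45, length.out = 50)
  rowsLin <- t(vapply(target, function(p) {
    nAlt <- round(p * n)
    c(rep(2, nAlt), rep(0, n - nAlt))
  }, numeric(n)))
  gdLin <- makeGD(rowsLin, pos = seq(1, 50) * 2e6)
  profLin <- mafProfile(gdLin, span = 0.75, gridPoints = 50)
  st <- siteStats(gdLin)
  ols <- lm(st$maf ~ I(st$pos_bp / 1e6))
  grid <- profLin$curve$pos_mb
  inner <- grid > quantile(grid, 0.15) & grid < quantile(grid, 0.85)
  pred <- cbind(1, grid) %*% coef(ols)
  expect_true(max(abs(profLin$curve$fit[inner] - pred[inner])) < 0.03)
})

test_that("a planted low-diversity region pulls the curve minimum into it", {
  cfg <- smallPopConfig(seed = 17, nAccessions = 150, nMarkers = 240)
  sim <- simulatePopulation(cfg)
  d <- dosages(sim$gd)
  si <- siteInfo(sim$gd)
  # crush diversity on c1 between 40 and 80 Mb: make those sites nearly
  # monomorphic
  inRegion <- si$chrom == "c1" & si$pos_bp >= 40e6 & si$pos_bp <= 80e6
  d[inRegion, ] <- 0
  d[inRegion, 1:3] <- 2
  gd2 <- GenotypeData(d, si, accessionInfo(sim$gd))
  prof <- mafProfile(gd2, span = 0.35)
  c1 <- prof$curve[prof$curve$chrom == "c1", ]
  expect_true(c1$pos_mb[which.min(c1$fit)] > 35 &&
                c1$pos_mb[which.min(c1$fit)] < 85)
})

test_that("chromosomes with too few sites yield points but no curve", {
  gd <- makeGD(rbind(c(0, 2, 0, 2), c(0, 0, 2, 2)), chrom = c("c1", "c1"))
  prof <- mafProfile(gd, minSites = 10)
  expect_identical(prof$skipped, "c1")
  expect_equal(nrow(prof$curve), 0)
  expect_equal(nrow(prof$points), 2)
})
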