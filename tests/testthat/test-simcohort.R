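test_that("invalid configurations are rejected by name", {
  expect_error(simConfig(nSamples = 0), "nSamples")
  expect_error(simConfig(afSpectrum = data.frame(lower = 0, upper = 1,
                                                 prop = 0.5)),
               "afSpectrum")
  expect_error(simConfig(errorModel = list(noCall = 1.5)), "errorModel")
  expect_error(simConfig(contamination = c("S0001:1" = 1)),
               "contamination")
})

test_that("a zero-frequency allele yields homozygous reference throughout", {
  cfg <- cleanConfig(50, 20, seed = 3, afSpectrum = pointSpectrum(0))
  truth <- simulateTruthCohort(cfg)
  expect_true(all(genotypes(truth) == "0/0"))
})

test_that("truth genotypes follow Hardy-Weinberg proportions", {
  ## single-locus binomial oracle at AF 0.5: hom-alt fraction ~ q^2 = 0.25
  cfg <- cleanConfig(10000, 1, seed = 5, afSpectrum = pointSpectrum(0.5))
  truth <- simulateTruthCohort(cfg)
  gt <- genotypes(truth)
  homAlt <- mean(gt == "1/1")
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(homAlt - 0.25), 3 * se)
  het <- mean(gt == "0/1")
  seh <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(het - 0.5), 3 * seh)
})

test_that("the same configuration and seed reproduce the cohort exactly", {
  cfg <- simConfig(nSamples = 10, nAssays = 150, seed = 17,
                   contamination = c("S0001:1" = 0.03))
  c1 <- simulateCohort(cfg)
  c2 <- simulateCohort(cfg)
  expect_identical(genotypes(c1$truth), genotypes(c2$truth))
  expect_identical(genotypes(c1$array$rep3), genotypes(c2$array$rep3))
  expect_identical(bafValues(c1$array$rep1), bafValues(c2$array$rep1))
  expect_identical(readDepth(c1$wgs), readDepth(c2$wgs))
})

test_that("the noiseless limit reproduces truth with call rate 1", {
  cfg <- cleanConfig(20, 200, seed = 9)
  co <- simulateCohort(cfg)
  for (k in 1:3)
    expect_identical(genotypes(co$array[[k]]), genotypes(co$truth))
  expect_true(all(callRate(co$array$rep1) == 1))
  expect_identical(genotypes(co$wgs), genotypes(co$truth))
})

test_that("injected false-positive rate is recovered at hom-ref truth", {
  e <- 0.01
  cfg <- cleanConfig(100, 2000, seed = 21, afSpectrum = pointSpectrum(0),
                     errorModel = list(fpHomRef = e),
                     errorMultipliers = c(transversion = 1))
  co <- simulateCohort(cfg)
  fpFrac <- mean(genotypes(co$array$rep1) != "0/0")
  n <- 100 * 2000
  se <- sqrt(e * (1 - e) / n)
  expect_lt(abs(fpFrac - e), 3 * se)
})

test_that("per-stratum multipliers scale the miscall rate", {
  base <- 5e-3
  cfg <- cleanConfig(80, 3000, seed = 33, afSpectrum = pointSpectrum(0),
                     errorModel = list(fpHomRef = base),
                     errorMultipliers = c(transversion = 4,
                                          complementary_tv = 1,
                                          INS = 1, DEL = 1, MAV = 1,
                                          lcr = 1),
                     variantTypeFractions = c(SNV = 1, INS = 0, DEL = 0,
                                              MAV = 0))
  co <- simulateCohort(cfg)
  ann <- annotateAssays(co$truth)
  gt <- genotypes(co$array$rep1)
  ts <- ann$change_class == "transition"
  rateTs <- mean(gt[ts, ] != "0/0")
  rateTv <- mean(gt[!ts, ] != "0/0")
  ## binomial 99% band around the configured per-stratum rates
  for (pair in list(list(rateTs, base, sum(ts) * 80),
                    list(rateTv, 4 * base, sum(!ts) * 80))) {
    se <- sqrt(pair[[2]] * (1 - pair[[2]]) / pair[[3]])
    expect_lt(abs(pair[[1]] - pair[[2]]), 2.576 * se)
  }
})

test_that("contamination displaces hom-ref BAF by alpha times the allele frequency", {
  alpha <- 0.05
  cfg <- cleanConfig(4, 4000, seed = 13, afSpectrum = pointSpectrum(0.5),
                     contamination = setNames(alpha, "S0002:1"))
  co <- simulateCohort(cfg)
  gt <- genotypes(co$truth)[, "S0002"]
  baf <- bafValues(co$array$rep1)[, "S0002"]
  homRef <- gt == "0/0"
  expect_gt(sum(homRef), 500)
  m <- mean(baf[homRef], na.rm = TRUE)
  expect_lt(abs(m - alpha * 0.5), 0.002)
  ## and hom-alt displaced downward from 1 by alpha * (1 - p)
  homAlt <- gt == "1/1"
  expect_lt(abs(mean(baf[homAlt], na.rm = TRUE) - (1 - alpha * 0.5)),
            0.002)
  ## uncontaminated replicate of the same sample stays at the poles
  baf2 <- bafValues(co$array$rep2)[, "S0002"]
  expect_lt(mean(baf2[homRef], na.rm = TRUE), 0.002)
})

test_that("WGS depth matches the configured mean and filters act on depth", {
  cfg <- simConfig(nSamples = 50, nAssays = 1000, seed = 29)
  truth <- simulateTruthCohort(cfg)
  wgs <- simulateWgsCalls(truth, cfg)
  dp <- readDepth(wgs)
  n <- sum(!is.na(dp))
  sdDp <- sqrt(37 + 37^2 / 40)
  expect_lt(abs(mean(dp, na.rm = TRUE) - 37), 3 * sdDp / sqrt(n))
  ## the depth floor removes exactly the calls below it
  masked <- maskLowConfidence(wgs, minDepth = 20, minQual = 0)
  lost <- is.na(genotypes(masked)) & !is.na(genotypes(wgs))
  expect_identical(unname(lost), unname(!is.na(dp) & dp < 20))
})

test_that("negative WGS depth is rejected", {
  expect_error(
    simulateWgsCalls(simulateTruthCohort(cleanConfig(2, 10, seed = 1)),
                     simConfig(wgsModel = list(meanDepth = -1))),
    "meanDepth")
})

test_that("realized stratum compositions track the configured fractions", {
  cfg <- simConfig(nSamples = 2, nAssays = 20000, seed = 71)
  truth <- simulateTruthCohort(cfg)
  md <- mcols(lociRanges(truth))
  expect_lt(abs(mean(md$variant_type == "SNV") - 656601 / 661126), 0.005)
  snv <- md$variant_type == "SNV"
  expect_lt(abs(mean(md$change_class[snv] == "transition") - 0.796), 0.01)
  expect_lt(abs(mean(md$cluster_qc_pass) - 0.92), 0.01)
  ## AF spectrum: realized bin shares match the configured proportions
  bins <- afBin(md$population_af)
  realized <- as.numeric(table(bins) / length(bins))
  expect_lt(max(abs(realized - simConfig()@afSpectrum$prop)), 0.015)
})

test_that("Hardy-Weinberg holds across loci under repeated seeds", {
  ## chi-square GoF non-significant at alpha = 0.01 for >= 95% of loci
  pvals <- c()
  for (seed in 1:4) {
    cfg <- cleanConfig(400, 250, seed = seed * 1000)
    truth <- simulateTruthCohort(cfg)
    gt <- genotypes(truth)
    af <- mcols(lociRanges(truth))$population_af
    snv <- mcols(lociRanges(truth))$variant_type == "SNV"
    for (i in which(snv & af > 0.05 & af < 0.95)) {
      p <- af[i]
      obs <- c(sum(gt[i, ] == "0/0"), sum(gt[i, ] == "0/1"),
               sum(gt[i, ] == "1/1"))
      expctd <- c((1 - p)^2, 2 * p * (1 - p), p^2)
      pvals <- c(pvals, suppressWarnings(
        chisq.test(obs, p = expctd)$p.value))
    }
  }
  expect_gt(length(pvals), 300)
  expect_gte(mean(pvals > 0.01), 0.95)
})
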