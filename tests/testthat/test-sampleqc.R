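test_that("call rate counts non-missing calls over eligible loci", {
  gt <- matrix("0/1", 100, 1, dimnames = list(NULL, "S1"))
  gm <- makeGm(gt)
  expect_equal(unname(callRate(gm)), 1)
  gt[1:2, 1] <- NA
  expect_equal(unname(callRate(makeGm(gt))), 0.98)
  gt[, 1] <- NA
  expect_equal(unname(callRate(makeGm(gt))), 0)
  expect_error(callRate(makeGm(gt, clusterPass = FALSE)),
               "zero eligible loci")
  ## ineligible (cluster-fail) loci do not enter the denominator
  gt2 <- matrix("0/1", 10, 1, dimnames = list(NULL, "S1"))
  gt2[1:5, 1] <- NA
  gm2 <- makeGm(gt2, clusterPass = c(rep(FALSE, 5), rep(TRUE, 5)))
  expect_equal(unname(callRate(gm2)), 1)
})

test_that("p10gc is the interpolated 10th percentile of called scores", {
  expect_equal(p10gc(rep(0.6, 5)), 0.6)
  expect_equal(p10gc(seq(0, 1, by = 0.1)), 0.1)
  ## sorting oracle: quantile at 0.10 with linear interpolation
  set.seed(4)
  x <- runif(37)
  s <- sort(x)
  h <- 1 + 0.10 * (length(x) - 1)
  manual <- s[floor(h)] + (h - floor(h)) * (s[ceiling(h)] - s[floor(h)])
  expect_equal(p10gc(x), manual)
  expect_error(p10gc(numeric(0)), "no scored calls")
})

test_that("higher chip rows have lower p10gc under the default gradient", {
  cfg <- simConfig(nSamples = 96, nAssays = 1500, seed = 8)
  co <- simulateCohort(cfg)
  qc <- sampleQC(co$array)
  byRow <- tapply(qc$p10gc, qc$chip_row, mean)
  expect_gt(byRow["1"], byRow["12"])
  ## the calibrated gradient lands near the expected per-row levels
  expect_lt(abs(byRow["1"] - 0.60), 0.02)
  expect_lt(abs(byRow["12"] - 0.55), 0.02)
})

test_that("het/hom ratio uses hom-alt as denominator and NA when absent", {
  gt <- matrix(c(rep("0/1", 10), rep("1/1", 5)), ncol = 1,
               dimnames = list(NULL, "S1"))
  expect_equal(unname(hetHomRatio(makeGm(gt))), 2)
  gt2 <- matrix(c(rep("0/0", 10), rep("1/1", 5)), ncol = 1,
                dimnames = list(NULL, "S1"))
  expect_equal(unname(hetHomRatio(makeGm(gt2))), 0)
  gt3 <- matrix("0/1", 5, 1, dimnames = list(NULL, "S1"))
  expect_true(is.na(hetHomRatio(makeGm(gt3))))
  ## HWE closed form at AF 0.5: 2pq / q^2 = 2
  cfg <- cleanConfig(1500, 60, seed = 12, afSpectrum = pointSpectrum(0.5))
  truth <- simulateTruthCohort(cfg)
  ratios <- hetHomRatio(truth)
  expect_lt(abs(mean(ratios) - 2), 0.15)
})

test_that("contamination estimator is exact on clean poles and recovers alpha", {
  ## baf exactly at the poles -> alpha-hat = 0
  n <- 200
  gt <- rep(c("0/0", "1/1"), each = n / 2)
  baf <- rep(c(0, 1), each = n / 2)
  af <- runif(n, 0.1, 0.9)
  expect_equal(estimateContamination(baf, gt, af), 0)
  ## too few homozygous calls -> undefined sentinel, not an error
  expect_true(is.na(estimateContamination(baf[1:50], gt[1:50], af[1:50])))
  ## simulator-injected alpha recovered within +/- 0.01
  alpha <- 0.03
  cfg <- simConfig(nSamples = 3, nAssays = 4000, seed = 19,
                   contamination = setNames(alpha, "S0002:1"))
  co <- simulateCohort(cfg)
  qc <- sampleQC(co$array)
  est <- qc$contamination[qc$sample_id == "S0002" & qc$replicate == 1]
  expect_lt(abs(est - alpha), 0.01)
  ## alpha = 0.04 is flagged at the default 0.025 threshold
  cfg2 <- simConfig(nSamples = 3, nAssays = 4000, seed = 23,
                    contamination = c("S0003:2" = 0.04))
  qc2 <- sampleQC(simulateArrayReplicates(simulateTruthCohort(cfg2), cfg2))
  hit <- qc2[qc2$sample_id == "S0003" & qc2$replicate == 2, ]
  expect_match(hit$flags, "CONTAMINATED")
  clean <- qc2[!(qc2$sample_id == "S0003" & qc2$replicate == 2), ]
  expect_false(any(grepl("CONTAMINATED", clean$flags)))
})

test_that("replicate z-scores match the direct mean/SD computation", {
  expect_true(all(replicateZscores(rep(0.97, 10))$zscore == 0))
  rates <- c(rep(0.99, 29), 0.90)
  z <- replicateZscores(rates, cutoff = -3)
  manual <- (rates - mean(rates)) / sd(rates)
  expect_equal(z$zscore, manual)
  expect_equal(which.min(z$zscore), 30)
  expect_true(z$z_outlier[30])
  expect_false(any(z$z_outlier[1:29]))
  ## standardization: mean 0, sd 1
  expect_equal(mean(z$zscore), 0)
  expect_equal(sd(z$zscore), 1)
  expect_error(replicateZscores(c(1, 1)), "at least 3")
})

test_that("dispersion is the population variance and order-invariant", {
  r <- c(0.9987, 0.9544, 0.9989)
  d <- replicateDispersion(r)
  expect_equal(round(d$mean, 3), 0.984)
  expect_equal(d$dispersion, mean((r - mean(r))^2))
  expect_equal(d$dispersion, 4.38086667e-4, tolerance = 1e-6)
  expect_equal(replicateDispersion(rev(r))$dispersion, d$dispersion)
  expect_equal(replicateDispersion(c(0.99, 0.99, 0.99))$dispersion, 0)
  expect_error(replicateDispersion(c(0.9, 0.9)), "exactly 3")
})

test_that("called plus missing genotypes partition the eligible assays", {
  cfg <- simConfig(nSamples = 15, nAssays = 800, seed = 31)
  co <- simulateCohort(cfg)
  nElig <- sum(mcols(lociRanges(co$truth))$cluster_qc_pass)
  for (k in 1:3) {
    gt <- genotypes(co$array[[k]])
    elig <- mcols(lociRanges(co$array[[k]]))$cluster_qc_pass
    called <- colSums(!is.na(gt[elig, ]))
    missing <- colSums(is.na(gt[elig, ]))
    expect_true(all(called + missing == nElig))
  }
})

test_that("chip-position summary aggregates per well and flags edges", {
  qc <- data.frame(sample_id = sprintf("S%02d", 1:24), replicate = 1,
                   call_rate = 0.99, p10gc = 0.6, contamination = 0.01,
                   chip_row = rep(1:12, 2), chip_col = rep(1:2, each = 12),
                   zscore = 0, flags = "")
  cps <- chipPositionSummary(qc)
  expect_equal(nrow(cps), 24)
  expect_true(all(cps$call_rate_mean == 0.99))
  expect_true(all(cps$call_rate_sd == 0 | is.na(cps$call_rate_sd)))
  expect_true(all(cps$edge_well[cps$chip_row %in% c(1, 12)]))
  ## z-outliers concentrate at degraded edge wells
  cfg <- simConfig(nSamples = 48, nAssays = 2000, seed = 41,
                   chipLayout = list(edgeNoCallRate = 0.08))
  co <- simulateCohort(cfg)
  qc2 <- sampleQC(co$array, zCutoff = -2)
  out <- qc2[qc2$zscore <= -2, ]
  expect_gt(nrow(out), 0)
  expect_true(all(out$chip_row >= 11 & out$chip_col == 1))
})

test_that("PCA separates divergent populations and is reproducible", {
  cfg <- cleanConfig(30, 1500, seed = 10)
  t1 <- simulateTruthCohort(cfg)
  loci <- lociRanges(t1)
  af <- mcols(loci)$population_af
  set.seed(99)
  af2 <- pmin(1, pmax(0, af + runif(length(af), -0.4, 0.4)))
  m1 <- matrix(rbinom(length(af2) * 30, 1, af2), length(af2))
  m2 <- matrix(rbinom(length(af2) * 30, 1, af2), length(af2))
  g2 <- matrix(paste(pmin(m1, m2), pmax(m1, m2), sep = "/"), length(af2))
  colnames(g2) <- sprintf("T%04d", 1:30)
  comb <- GenotypeMatrix(cbind(genotypes(t1), g2), loci)
  pc <- pcaStructure(comb, seed = 1)
  km <- kmeans(pc[, 1], 2, nstart = 5)
  lab <- rep(1:2, each = 30)
  agree <- max(mean(km$cluster == lab), mean(km$cluster == 3 - lab))
  expect_gte(agree, 0.99)
  ## silhouette-like separation on PC1
  d1 <- pc[1:30, 1]; d2 <- pc[31:60, 1]
  gap <- abs(mean(d1) - mean(d2))
  expect_gt(gap, 2 * (sd(d1) + sd(d2)))
  ## duplicated samples land on identical coordinates
  dup <- GenotypeMatrix(cbind(genotypes(t1)[, 1, drop = FALSE],
                              DUP = genotypes(t1)[, 1],
                              genotypes(t1)[, 2:6]), loci)
  pcd <- pcaStructure(dup, seed = 1)
  expect_equal(unname(pcd[1, ]), unname(pcd[2, ]))
  ## subsampled and full PCA agree on the partition
  pcSub <- pcaStructure(comb, nSubsample = 600, seed = 3)
  kmSub <- kmeans(pcSub[, 1], 2, nstart = 5)
  agreeSub <- max(mean(kmSub$cluster == km$cluster),
                  mean(kmSub$cluster == 3 - km$cluster))
  expect_gte(agreeSub, 0.99)
})

test_that("replicate summary combines call rates with concordance", {
  cfg <- simConfig(nSamples = 8, nAssays = 500, seed = 55)
  co <- simulateCohort(cfg)
  qc <- sampleQC(co$array)
  conc <- pairwiseReplicateConcordance(co$array)
  rs <- replicateSummary(qc, conc)
  expect_equal(nrow(rs), 8)
  expect_true(all(rs$dispersion >= 0))
  expect_true(all(c("r1r2", "r2r3", "r1r3") %in% names(rs)))
  m <- rowMeans(as.matrix(rs[, c("r1_call_rate", "r2_call_rate",
                                 "r3_call_rate")]))
  expect_equal(rs$mean_call_rate, m)
})
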