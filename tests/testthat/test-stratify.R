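test_that("variant types classify by allele shape", {
  expect_equal(classifyVariantType("A", "G"), "SNV")
  expect_equal(classifyVariantType("A", "G,T"), "MAV")
  expect_equal(classifyVariantType("ACG", "A"), "DEL")
  expect_equal(classifyVariantType("A", "AT"), "INS")
  expect_warning(out <- classifyVariantType("AC", "GT"), "MNV")
  expect_equal(out, "MNV")
})

test_that("the 12 substitutions split 4/8 into transitions/transversions", {
  grid <- expand.grid(ref = c("A", "C", "G", "T"),
                      alt = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  cc <- classifySnvChange(grid$ref, grid$alt)
  expect_equal(sum(cc$change_class == "transition"), 4)
  expect_equal(sum(cc$change_class == "transversion"), 8)
  expect_equal(sum(cc$complementary_tv), 4)
  expect_true(all(cc$change_class[cc$complementary_tv] == "transversion"))
  expect_equal(classifySnvChange("A", "G")$change_class, "transition")
  ctv <- classifySnvChange(c("A", "T", "C", "G"), c("T", "A", "G", "C"))
  expect_true(all(ctv$complementary_tv))
  expect_error(classifySnvChange("A", "N"), "single bases")
  expect_error(classifySnvChange("A", "A"), "must differ")
})

test_that("allele-frequency bins partition [0,1] with the printed edges", {
  expect_equal(as.character(afBin(0)), "[0-0.1%]")
  expect_equal(as.character(afBin(0.001)), "[0-0.1%]")
  expect_equal(as.character(afBin(0.0011)), "(0.1-1%]")
  expect_equal(as.character(afBin(0.05)), "(1-5%]")
  expect_equal(as.character(afBin(0.9)), "(80-90%]")
  expect_equal(as.character(afBin(1)), "(90-100%]")
  expect_error(afBin(1.2), "\\[0, 1\\]")
  expect_error(afBin(-0.1), "\\[0, 1\\]")
  ## exhaustive partition: a fine grid plus every edge and its
  ## neighborhood maps to exactly one of the 13 bins
  edges <- c(0, 0.001, 0.01, 0.05, seq(0.1, 1, by = 0.1))
  af <- sort(unique(c(seq(0, 1, by = 0.0005), edges,
                      pmin(1, edges + 1e-9), pmax(0, edges - 1e-9))))
  bins <- afBin(af)
  expect_false(any(is.na(bins)))
  expect_equal(nlevels(bins), 13)
  expect_setequal(as.character(unique(bins)), levels(bins))
  ## monotone: bin index never decreases with af
  expect_true(all(diff(as.integer(bins)) >= 0))
})

test_that("LCR intersection honors the 0-based half-open convention", {
  loci <- GRanges("1", IRanges(c(100, 101, 150), width = 1))
  mcols(loci) <- DataFrame(assay_id = c("a", "b", "c"),
                           ref = "A", alt = "G", cluster_qc_pass = TRUE)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t99\t100", "1\t100\t120"), bed)
  flags <- intersectLcr(loci, list(SimpleRepeat = bed))
  ## position 100 hits (99,100); position 101 hits (100,120);
  ## position 150 hits nothing
  expect_equal(unname(flags[, "SimpleRepeat"]), c(TRUE, TRUE, FALSE))
  bed2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("1\t100\t200", bed2)
  flags2 <- intersectLcr(loci, list(x = bed2))
  expect_equal(unname(flags2[, "x"]), c(FALSE, TRUE, TRUE))
})

test_that("LCR flags agree with a brute-force interval scan", {
  set.seed(11)
  nL <- 300
  loci <- GRanges("1", IRanges(sample.int(5000, nL), width = 1))
  mcols(loci) <- DataFrame(assay_id = sprintf("A%03d", seq_len(nL)),
                           ref = "A", alt = "G", cluster_qc_pass = TRUE)
  starts <- sort(sample.int(5000, 40))
  ends <- starts + sample.int(60, 40, replace = TRUE)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste("1", starts, ends, sep = "\t"), bed)
  got <- intersectLcr(loci, list(cls = bed))[, "cls"]
  pos <- start(loci)
  manual <- vapply(pos, function(p)
    any(p - 1 >= starts & p - 1 < ends), logical(1))
  expect_identical(unname(got), manual)
})

test_that("stratified metrics aggregate per stratum and cover all assays", {
  set.seed(13)
  cfg <- simConfig(nSamples = 20, nAssays = 1200, seed = 47)
  co <- simulateCohort(cfg)
  pa <- perAssayMetrics(co$array$rep1, co$truth)
  ann <- annotateAssays(co$truth)
  st <- stratifiedMetrics(pa, ann, "change_class")
  expect_setequal(st$stratum, c("transition", "transversion"))
  snvInScope <- sum(!is.na(ann$change_class[match(pa$assay_id,
                                                  ann$assay_id)]))
  expect_equal(sum(st$n_assays), snvInScope)
  expect_true(all(st$frac_ppv_1 + st$frac_ppv_lt1 == 1))
  ## single stratum equals the global summary
  one <- stratifiedMetrics(pa, transform(ann, g = "all"), "g")
  expect_equal(one$n_assays, nrow(pa))
  expect_equal(one$ppv_mean, mean(pa$ppv, na.rm = TRUE))
  expect_error(stratifiedMetrics(pa, ann, "nonexistent"), "unknown")
})

test_that("higher transversion error lowers the transversion stratum PPV", {
  cfg <- cleanConfig(150, 2500, seed = 83,
                     afSpectrum = pointSpectrum(0.3),
                     errorModel = list(fpHomRef = 1e-3, hetToHom = 1e-3),
                     errorMultipliers = c(transversion = 25,
                                          complementary_tv = 1, INS = 1,
                                          DEL = 1, MAV = 1, lcr = 1),
                     variantTypeFractions = c(SNV = 1, INS = 0, DEL = 0,
                                              MAV = 0))
  co <- simulateCohort(cfg)
  pa <- perAssayMetrics(co$array$rep1, co$truth)
  ann <- annotateAssays(co$truth)
  st <- stratifiedMetrics(pa, ann, "change_class")
  expect_lt(st$ppv_median[st$stratum == "transversion"],
            st$ppv_median[st$stratum == "transition"])
  expect_lt(st$frac_ppv_1[st$stratum == "transversion"],
            st$frac_ppv_1[st$stratum == "transition"])
})

test_that("the panel filter chain is sequential with non-increasing counts", {
  ann <- data.frame(assay_id = sprintf("A%02d", 1:10),
                    chrom = "1", pos = c(seq(500, 5000, length.out = 8),
                                         90000, 95000),
                    clinvar_path = c(rep(TRUE, 6), rep(FALSE, 2),
                                     TRUE, TRUE),
                    hgmd = c(rep(TRUE, 4), rep(FALSE, 4), TRUE, TRUE),
                    curated_mvl = c(rep(TRUE, 2), rep(FALSE, 6),
                                    TRUE, TRUE))
  tx <- data.frame(gene = "G1", chrom = "1", tx_start = 1000,
                   tx_end = 4000)
  res <- selectMapPanel(ann, tx, flank = 1000)
  expect_equal(res$report$step,
               c("transcript_window", "clinvar_pathogenic", "hgmd",
                 "curated_mvl"))
  ## positions 500..5000 fall inside [0, 5000]; the two 9xxxx do not
  expect_equal(res$report$n_assays, c(8, 6, 4, 2))
  expect_true(all(diff(res$report$n_assays) <= 0))
  expect_equal(res$assays, c("A01", "A02"))
  ## all-flag case: counts constant after the window step
  ann2 <- transform(ann, clinvar_path = TRUE, hgmd = TRUE,
                    curated_mvl = TRUE)
  res2 <- selectMapPanel(ann2, tx)
  expect_true(all(res2$report$n_assays == 8))
  expect_error(selectMapPanel(ann, tx[0, ]), "empty transcript")
})

test_that("percentages round half away from zero at the printed precision", {
  expect_equal(percentSummary(610771, 661126), 92)
  expect_equal(percentSummary(1368, 2065), 66)
  expect_equal(percentSummary(0, 10), 0)
  expect_equal(percentSummary(25, 1000), 3)     # 2.5 -> 3, not banker's 2
  expect_equal(percentSummary(15, 1000, 1), 1.5)
  expect_equal(percentSummary(476707, 594346), 80)
  expect_true(is.na(percentSummary(5, 0)))
})
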