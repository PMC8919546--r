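## Shared fixture builders: tiny GenotypeMatrix objects and configs built
## in code, plus an independent brute-force pair classifier used as an
## oracle against the vectorized implementation.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(SummarizedExperiment)
})

## a GenotypeMatrix from a genotype-code matrix and plain locus fields
makeGm <- function(gt, ref = NULL, alt = NULL, chrom = NULL, pos = NULL,
                   af = NULL, clusterPass = TRUE, ...) {
  nL <- nrow(gt)
  if (is.null(ref)) ref <- rep("A", nL)
  if (is.null(alt)) alt <- rep("G", nL)
  if (is.null(chrom)) chrom <- rep("1", nL)
  if (is.null(pos)) pos <- seq(100, by = 100, length.out = nL)
  loci <- GRanges(chrom, IRanges(pos, width = 1))
  mcols(loci) <- DataFrame(assay_id = sprintf("A%04d", seq_len(nL)),
                           ref = ref, alt = alt,
                           cluster_qc_pass = rep_len(clusterPass, nL),
                           population_af = if (is.null(af))
                             rep(NA_real_, nL) else af)
  GenotypeMatrix(gt, loci, ...)
}

## random genotype-code matrix over the biallelic codes plus NA
randomGtMatrix <- function(nL, nS, naProb = 0.05,
                           codes = c("0/0", "0/1", "1/1")) {
  gt <- matrix(sample(codes, nL * nS, replace = TRUE), nL, nS)
  gt[matrix(runif(nL * nS) < naProb, nL, nS)] <- NA_character_
  colnames(gt) <- sprintf("S%03d", seq_len(nS))
  gt
}

## independent per-pair classifier: plain conditionals, no vectorization,
## kept deliberately separate from the package implementation
bruteClassify <- function(test, truth) {
  if (is.na(test) || is.na(truth)) return("na")
  testAlt <- test != "0/0"
  truthAlt <- truth != "0/0"
  if (!testAlt && !truthAlt) return("tn")
  if (test == truth) return("tp")
  if (testAlt && !truthAlt) return("fp")
  if (!testAlt && truthAlt) return("fn")
  "x"
}

bruteTally <- function(testM, truthM) {
  counts <- c(a = 0, b = 0, c = 0, d = 0, z = 0, n_na = 0)
  map <- c(tp = "a", fp = "b", tn = "c", fn = "d", x = "z", na = "n_na")
  for (i in seq_len(nrow(testM)))
    for (j in seq_len(ncol(testM))) {
      lbl <- bruteClassify(testM[i, j], truthM[i, j])
      counts[map[lbl]] <- counts[map[lbl]] + 1
    }
  counts
}

## a single-bin AF spectrum fixing every locus at frequency `af`
pointSpectrum <- function(af)
  data.frame(lower = af, upper = af, prop = 1)

## an error-free configuration (no miscalls, no no-calls, no edge or
## contamination effects)
cleanConfig <- function(nSamples, nAssays, seed, ...) {
  dots <- list(...)
  em <- list(hetToHom = 0, homToHet = 0, fpHomRef = 0, fnAlt = 0,
             noCall = 0)
  if (!is.null(dots$errorModel))
    em <- utils::modifyList(em, dots$errorModel)
  dots$errorModel <- em
  wm <- list(errorRate = 0, noCall = 0, assayDropout = 0)
  if (!is.null(dots$wgsModel)) wm <- utils::modifyList(wm, dots$wgsModel)
  dots$wgsModel <- wm
  cl <- list(edgeNoCallRate = 0)
  if (!is.null(dots$chipLayout))
    cl <- utils::modifyList(cl, dots$chipLayout)
  dots$chipLayout <- cl
  if (is.null(dots$clusterQcFailRate)) dots$clusterQcFailRate <- 0
  do.call(simConfig,
          c(list(nSamples = nSamples, nAssays = nAssays, seed = seed),
            dots))
}
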