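## Synthetic-cohort generation: Hardy-Weinberg truth genotypes over a
## configured AF spectrum, triplicate array call sets with per-stratum
## error, contamination as BAF mixing, chip-layout quality gradients, and
## an independent WGS-like call set.

.BASES <- c("A", "C", "G", "T")
.TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
.COMPL      <- c(A = "T", T = "A", C = "G", G = "C")
.TV_OTHER   <- c(A = "C", C = "A", G = "T", T = "G")

## draw an allele index matrix (loci x samples) under HWE given per-locus
## cumulative allele probabilities (ref, alt1, alt2, alt3)
.drawAlleles <- function(cum1, cum2, cum3, n) {
  u <- matrix(runif(length(cum1) * n), nrow = length(cum1))
  (u > cum1) + (u > cum2) + (u > cum3)
}

.codeFromAlleles <- function(a1, a2)
  paste(pmin(a1, a2), pmax(a1, a2), sep = "/")

#' Simulate the truth cohort
#'
#' Draws an assay panel (loci with ref/alt alleles, strata labels, panel
#' flags and population alternate-allele frequencies following the
#' configured spectrum) and, independently per sample, unphased truth
#' genotypes under Hardy-Weinberg equilibrium at each locus. For
#' multi-allelic assays the total alternate frequency is split equally
#' among the alternate alleles. A synthetic transcript table for the
#' actionable-gene panel is attached as
#' \code{metadata(.)$transcripts}. Deterministic for a fixed
#' \code{config@seed}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{GenotypeMatrix} of truth genotypes whose row
#'   metadata carry \code{population_af}, \code{variant_type},
#'   \code{change_class}, \code{complementary_tv}, the low-complexity
#'   flags (\code{lcr_SimpleRepeat}, \code{lcr_Microsatellite},
#'   \code{lcr_RepeatMasker}) and panel flags
#'   (\code{in_transcript_window}, \code{clinvar_path}, \code{hgmd},
#'   \code{curated_mvl}).
#' @export
simulateTruthCohort <- function(config) {
  validObject(config)
  set.seed(config@seed)
  nL <- config@nAssays
  nS <- config@nSamples

  chrom <- sort(sample(.AUTOSOMES, nL, replace = TRUE))
  pos <- integer(nL)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pos[i] <- sort(sample.int(2e7, length(i)))
  }

  vt <- sample(names(config@variantTypeFractions), nL, replace = TRUE,
               prob = config@variantTypeFractions)
  ref <- sample(.BASES, nL, replace = TRUE)
  alt <- character(nL)
  change <- rep(NA_character_, nL)
  compTv <- rep(FALSE, nL)

  isSnv <- vt == "SNV"
  isTs <- isSnv & (runif(nL) < config@transitionFraction)
  alt[isTs] <- .TS_PARTNER[ref[isTs]]
  change[isTs] <- "transition"
  isTv <- isSnv & !isTs
  isCtv <- isTv & (runif(nL) < config@complementaryTvFraction)
  alt[isCtv] <- .COMPL[ref[isCtv]]
  alt[isTv & !isCtv] <- .TV_OTHER[ref[isTv & !isCtv]]
  change[isTv] <- "transversion"
  compTv[isCtv] <- TRUE

  for (i in which(vt == "INS")) {
    alt[i] <- paste0(ref[i], paste(sample(.BASES, sample(1:3, 1),
                                          replace = TRUE), collapse = ""))
  }
  for (i in which(vt == "DEL")) {
    anchor <- sample(.BASES, 1)
    ref[i] <- paste0(anchor, paste(sample(.BASES, sample(1:3, 1),
                                          replace = TRUE), collapse = ""))
    alt[i] <- anchor
  }
  for (i in which(vt == "MAV")) {
    k <- if (runif(1) < 0.8) 2L else 3L
    alt[i] <- paste(sample(setdiff(.BASES, ref[i]), k), collapse = ",")
  }

  sp <- config@afSpectrum
  bin <- sample.int(nrow(sp), nL, replace = TRUE, prob = sp$prop)
  af <- sp$lower[bin] + runif(nL) * (sp$upper[bin] - sp$lower[bin])

  lcr <- matrix(runif(nL * length(config@lcrFractions)) <
                  rep(config@lcrFractions, each = nL),
                nrow = nL,
                dimnames = list(NULL, names(config@lcrFractions)))
  clusterPass <- runif(nL) >= config@clusterQcFailRate

  ## actionable-gene panel: windows centered on randomly chosen assays
  pm <- config@panelModel
  nG <- min(pm$nGenes, nL)
  centers <- sample.int(nL, nG)
  transcripts <- data.frame(
    gene = sprintf("GENE%02d", seq_len(nG)),
    chrom = chrom[centers],
    tx_start = pmax(1L, pos[centers] - as.integer(pm$geneWidth / 2)),
    tx_end = pos[centers] + as.integer(pm$geneWidth / 2),
    stringsAsFactors = FALSE)
  inWin <- rep(FALSE, nL)
  for (g in seq_len(nG)) {
    inWin <- inWin | (chrom == transcripts$chrom[g] &
                      pos >= transcripts$tx_start[g] - pm$flank &
                      pos <= transcripts$tx_end[g] + pm$flank)
  }
  clinvar <- inWin & (runif(nL) < pm$pClinvar)
  hgmd <- clinvar & (runif(nL) < pm$pHgmd)
  curated <- hgmd & (runif(nL) < pm$pCurated)

  nAlt <- lengths(strsplit(alt, ",", fixed = TRUE))
  pAlt <- af / nAlt
  pRef <- 1 - af
  cum1 <- pRef
  cum2 <- pRef + ifelse(nAlt >= 1, pAlt, 0)
  cum3 <- cum2 + ifelse(nAlt >= 2, pAlt, 0)
  a1 <- .drawAlleles(cum1, cum2, cum3, nS)
  a2 <- .drawAlleles(cum1, cum2, cum3, nS)
  gt <- matrix(.codeFromAlleles(a1, a2), nrow = nL)
  colnames(gt) <- sprintf("S%04d", seq_len(nS))

  loci <- GRanges(chrom, IRanges(pos, width = 1))
  mcols(loci) <- DataFrame(
    assay_id = sprintf("GSA%07d", seq_len(nL)),
    ref = ref, alt = alt, cluster_qc_pass = clusterPass,
    population_af = af, variant_type = vt, change_class = change,
    complementary_tv = compTv,
    lcr_SimpleRepeat = lcr[, "SimpleRepeat"],
    lcr_Microsatellite = lcr[, "Microsatellite"],
    lcr_RepeatMasker = lcr[, "RepeatMasker"],
    in_transcript_window = inWin, clinvar_path = clinvar,
    hgmd = hgmd, curated_mvl = curated)
  out <- GenotypeMatrix(gt, loci, replicateId = "truth")
  metadata(out)$transcripts <- transcripts
  metadata(out)$config_seed <- config@seed
  out
}

## per-locus miscall multiplier from the stratum labels
.lociErrorMultiplier <- function(loci, mult) {
  md <- mcols(loci)
  m <- rep(1, length(loci))
  g <- function(nm) if (nm %in% names(mult)) mult[[nm]] else 1
  m[!is.na(md$change_class) & md$change_class == "transversion"] <-
    m[!is.na(md$change_class) & md$change_class == "transversion"] * g("transversion")
  m[md$complementary_tv %in% TRUE] <-
    m[md$complementary_tv %in% TRUE] * g("complementary_tv")
  for (ty in c("INS", "DEL", "MAV"))
    m[md$variant_type == ty] <- m[md$variant_type == ty] * g(ty)
  inLcr <- (md$lcr_SimpleRepeat %in% TRUE) |
    (md$lcr_Microsatellite %in% TRUE) | (md$lcr_RepeatMasker %in% TRUE)
  m[inLcr] <- m[inLcr] * g("lcr")
  m
}

## chip placement for one replicate: wells filled column-major, 24 per chip
.chipAssign <- function(sampleIds, replicate, layout) {
  n <- length(sampleIds)
  perChip <- as.integer(layout$rows * layout$cols)
  idx <- seq_len(n) - 1L
  within <- idx %% perChip
  data.frame(sample_id = sampleIds, replicate = replicate,
             chip_id = sprintf("R%d_CHIP%03d", replicate,
                               idx %/% perChip + 1L),
             chip_row = as.integer(within %% layout$rows + 1L),
             chip_col = as.integer(within %/% layout$rows + 1L),
             stringsAsFactors = FALSE)
}

#' Simulate triplicate array call sets
#'
#' Applies the configured per-call error model to the truth genotypes,
#' independently per replicate and per call, with per-stratum multipliers
#' on the miscall probabilities. Error events are mutually exclusive and
#' applied in the order no-call, then miscall. Per-call GenCall-like
#' scores are Beta-distributed with a mean that declines linearly with
#' chip row; B-allele frequencies are drawn around 0 / 0.5 / 1 by truth
#' zygosity and, for a contaminated sample-replicate with mixing fraction
#' alpha, displaced toward the population allele frequency at homozygous
#' loci (hom-ref mean \code{alpha * p}, hom-alt mean
#' \code{1 - alpha * (1 - p)}). Contaminated replicates also suffer an
#' elevated no-call rate (\code{1.5 * alpha}), and the two bottom rows of
#' chip column 1 an extra \code{edgeNoCallRate}, so positional and
#' contamination outliers are detectable downstream.
#'
#' @param truth truth cohort from \code{\link{simulateTruthCohort}}.
#' @param config the same \linkS4class{SimConfig}.
#' @return named list of \code{nReplicates}
#'   \linkS4class{GenotypeMatrix} objects (\code{rep1}, \code{rep2}, ...)
#'   with \code{GT}, \code{GC} and \code{BAF} assays and chip placement in
#'   \code{colData}.
#' @export
simulateArrayReplicates <- function(truth, config) {
  validObject(config)
  if (length(config@contamination) &&
      (any(config@contamination < 0) || any(config@contamination >= 1)))
    stop("contamination fractions must lie in [0, 1)")
  set.seed(config@seed + 1)
  loci <- rowRanges(truth)
  tgt <- genotypes(truth)
  nL <- nrow(tgt); nS <- ncol(tgt)
  sampleIds <- colnames(tgt)
  af <- mcols(loci)$population_af
  mult <- .lociErrorMultiplier(loci, config@errorMultipliers)
  em <- config@errorModel
  lay <- config@chipLayout

  ta1 <- matrix(as.integer(substr(tgt, 1, 1)), nrow = nL)
  ta2 <- matrix(as.integer(substr(tgt, 3, 3)), nrow = nL)
  isHomRef <- ta1 == 0L & ta2 == 0L
  isHet <- ta1 != ta2
  isHomAlt <- !isHomRef & !isHet

  reps <- vector("list", config@nReplicates)
  names(reps) <- sprintf("rep%d", seq_len(config@nReplicates))
  for (r in seq_len(config@nReplicates)) {
    sheet <- .chipAssign(sampleIds, r, lay)
    alpha <- setNames(rep(0, nS), sampleIds)
    key <- paste0(sampleIds, ":", r)
    hit <- match(names(config@contamination), key)
    alpha[hit[!is.na(hit)]] <- config@contamination[!is.na(hit)]

    ## no-call probability per cell: base + edge + contamination boost
    pnc <- matrix(em$noCall, nL, nS)
    edge <- sheet$chip_row >= lay$rows - 1L & sheet$chip_col == 1L
    pnc[, edge] <- pnc[, edge] + lay$edgeNoCallRate
    pnc <- pnc + rep(1.5 * alpha, each = nL)
    noCall <- matrix(runif(nL * nS), nL) < pnc

    ## miscalls, mutually exclusive per call, rates scaled per stratum
    u <- matrix(runif(nL * nS), nL)
    u3 <- matrix(runif(nL * nS), nL)
    gt <- tgt
    pm <- mult  # recycled column-wise
    i <- isHomRef & u < pmin(1, em$fpHomRef * pm)
    gt[i] <- "0/1"
    p1 <- pmin(1, em$hetToHom * pm)
    p2 <- pmin(1, (em$hetToHom + em$fnAlt) * pm)
    i <- isHet & u < p1
    gt[i] <- ifelse(u3[i] < 0.5,
                    .codeFromAlleles(ta1[i], ta1[i]),
                    .codeFromAlleles(ta2[i], ta2[i]))
    i <- isHet & u >= p1 & u < p2
    gt[i] <- "0/0"
    q1 <- pmin(1, em$homToHet * pm)
    q2 <- pmin(1, (em$homToHet + em$fnAlt) * pm)
    i <- isHomAlt & u < q1
    gt[i] <- .codeFromAlleles(0L, ta1[i])
    i <- isHomAlt & u >= q1 & u < q2
    gt[i] <- "0/0"
    gt[noCall] <- NA_character_

    ## GenCall-like scores: Beta with row-dependent mean
    rowFrac <- (sheet$chip_row - 1) / max(1, lay$rows - 1)
    mu <- lay$gcMeanRow1 + rowFrac * (lay$gcMeanRowMax - lay$gcMeanRow1)
    k <- lay$gcConcentration
    gc <- matrix(rbeta(nL * nS, rep(mu * k, each = nL),
                       rep((1 - mu) * k, each = nL)), nL)
    gc <- round(gc, 4)

    ## BAF: truth zygosity + contamination displacement + noise.
    ## Homozygous calls sit at their pole displaced by alpha times the
    ## frequency of the unobserved allele; noise on the displacement is
    ## mostly multiplicative (tight clusters at the poles), the het
    ## cluster is a wider Gaussian around 0.5.
    bm <- config@bafModel
    aMat <- rep(alpha, each = nL)
    disp <- matrix(0, nL, nS)
    disp[isHomRef] <- (aMat * af)[isHomRef]
    disp[isHomAlt] <- (aMat * (1 - af))[isHomAlt]
    rel <- matrix(rnorm(nL * nS, mean = 1, sd = bm$relSd), nL)
    addn <- matrix(rnorm(nL * nS, sd = bm$homSd), nL)
    baf <- matrix(0.5 + rnorm(nL * nS, sd = bm$hetSd), nL)
    baf[isHomRef] <- (disp * rel + addn)[isHomRef]
    baf[isHomAlt] <- (1 - disp * rel + addn)[isHomAlt]
    baf[baf < 0] <- 0
    baf[baf > 1] <- 1
    baf <- round(baf, 4)

    gc[is.na(gt)] <- NA_real_
    baf[is.na(gt)] <- NA_real_
    colnames(gt) <- sampleIds
    cd <- DataFrame(sheet[, c("chip_id", "chip_row", "chip_col")],
                    row.names = sampleIds)
    reps[[r]] <- GenotypeMatrix(gt, loci, sampleData = cd, gc = gc,
                                baf = baf,
                                replicateId = sprintf("rep%d", r))
  }
  reps
}

#' Simulate an independent WGS-like call set
#'
#' Draws per-call read depth (negative binomial around
#' \code{wgsModel$meanDepth}), Phred-scaled genotype quality (truncated
#' Gaussian), injects genotype errors at \code{wgsModel$errorRate}
#' (replacing the call with a different genotype over the same alleles)
#' and no-calls at \code{wgsModel$noCall}; a small fraction of assays
#' (\code{assayDropout}) is made systematically missing in
#' \code{dropoutMissingRate} of samples, emulating assays poorly covered
#' by sequencing. Deterministic for \code{config@seed + 2}.
#'
#' @inheritParams simulateArrayReplicates
#' @return a \linkS4class{GenotypeMatrix} with \code{GT}, \code{DP} and
#'   \code{GQ} assays.
#' @export
simulateWgsCalls <- function(truth, config) {
  validObject(config)
  wm <- config@wgsModel
  if (wm$meanDepth < 0) stop("wgsModel$meanDepth must be non-negative")
  set.seed(config@seed + 2)
  loci <- rowRanges(truth)
  gt <- genotypes(truth)
  nL <- nrow(gt); nS <- ncol(gt)

  depth <- matrix(rnbinom(nL * nS, mu = wm$meanDepth,
                          size = wm$depthDispersion), nL)
  qual <- matrix(pmin(99, pmax(0, round(rnorm(nL * nS, wm$qualMean,
                                              wm$qualSd)))), nL)

  if (wm$errorRate > 0) {
    err <- which(matrix(runif(nL * nS), nL) < wm$errorRate & !is.na(gt))
    if (length(err)) {
      row <- (err - 1L) %% nL + 1L
      cur <- gt[err]
      pick <- vapply(seq_along(err), function(j) {
        opts <- setdiff(c("0/0", "0/1", "1/1"), cur[j])
        opts[sample.int(length(opts), 1)]
      }, character(1))
      gt[err] <- pick
    }
  }
  miss <- matrix(runif(nL * nS), nL) < wm$noCall
  if (wm$assayDropout > 0) {
    drop <- runif(nL) < wm$assayDropout
    if (any(drop))
      miss[drop, ] <- miss[drop, , drop = FALSE] |
        (matrix(runif(sum(drop) * nS), sum(drop), nS) <
           wm$dropoutMissingRate)
  }
  gt[miss] <- NA_character_
  depth[is.na(gt)] <- NA_real_
  qual[is.na(gt)] <- NA_real_
  colnames(gt) <- colnames(genotypes(truth))
  GenotypeMatrix(gt, loci, depth = depth, qual = qual,
                 replicateId = "wgs")
}

#' Simulate a full cohort in one call
#'
#' Convenience wrapper running \code{\link{simulateTruthCohort}},
#' \code{\link{simulateArrayReplicates}} and
#' \code{\link{simulateWgsCalls}}.
#'
#' @inheritParams simulateTruthCohort
#' @return list with elements \code{truth}, \code{array} (list of
#'   replicate \linkS4class{GenotypeMatrix}) and \code{wgs}.
#' @export
simulateCohort <- function(config) {
  truth <- simulateTruthCohort(config)
  list(truth = truth,
       array = simulateArrayReplicates(truth, config),
       wgs = simulateWgsCalls(truth, config))
}
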