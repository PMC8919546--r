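## Per-sample / per-replicate quality control: call rate, p10GC,
## het/hom ratio, BAF-based contamination estimation, replicate z-scores
## and dispersion, chip-position aggregation, PCA structure check.

#' Per-sample genotype call rate
#'
#' Fraction of eligible assays (cluster-QC pass, by default) with a
#' non-missing genotype, per sample.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param eligibleOnly restrict to cluster-QC-pass assays.
#' @return named numeric vector, one value per sample.
#' @export
callRate <- function(x, eligibleOnly = TRUE) {
  gt <- genotypes(x)
  if (eligibleOnly) {
    keep <- mcols(rowRanges(x))$cluster_qc_pass %in% TRUE
    gt <- gt[keep, , drop = FALSE]
  }
  if (nrow(gt) == 0)
    stop("call rate undefined: zero eligible loci")
  colMeans(!is.na(gt))
}

#' 10th percentile of per-call quality scores
#'
#' p10GC is the 10th percentile (linear interpolation between order
#' statistics) of the GenCall-like scores over called genotypes.
#'
#' @param x a numeric vector of scores, or a
#'   \linkS4class{GenotypeMatrix} with a \code{GC} assay (then one value
#'   per sample is returned).
#' @return numeric scalar, or named vector per sample.
#' @export
p10gc <- function(x) {
  if (is(x, "GenotypeMatrix")) {
    gc <- gcScores(x)
    if (is.null(gc)) stop("no GC scores in this dataset")
    gc[is.na(genotypes(x))] <- NA_real_
    return(apply(gc, 2, p10gc))
  }
  x <- x[!is.na(x)]
  if (!length(x)) stop("p10gc undefined: no scored calls")
  unname(quantile(x, 0.10, type = 7))
}

#' Heterozygote to homozygote-alternate ratio
#'
#' Number of heterozygous calls over the number of homozygous-alternate
#' calls (any homozygous genotype different from homozygous reference),
#' per sample, over autosomal eligible assays. Returns \code{NA} for a
#' sample with zero homozygous-alternate calls.
#'
#' @inheritParams callRate
#' @param autosomesOnly restrict to autosomes.
#' @return named numeric vector per sample.
#' @export
hetHomRatio <- function(x, eligibleOnly = TRUE, autosomesOnly = TRUE) {
  keep <- rep(TRUE, nrow(x))
  if (eligibleOnly)
    keep <- keep & (mcols(rowRanges(x))$cluster_qc_pass %in% TRUE)
  if (autosomesOnly) keep <- keep & .isAutosome(x)
  gt <- genotypes(x)[keep, , drop = FALSE]
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  het <- colSums(!is.na(gt) & a1 != a2)
  homAlt <- colSums(!is.na(gt) & a1 == a2 & a1 != "0")
  ifelse(homAlt > 0, het / homAlt, NA_real_)
}

#' Estimate sample contamination from B-allele frequencies
#'
#' Under two-sample DNA mixing with fraction \code{alpha}, the expected
#' BAF displacement at a homozygous call is \code{alpha} times the
#' population frequency of the unobserved allele: at hom-ref calls
#' \code{d = baf} with \code{q = p} (the alternate allele frequency), at
#' hom-alt calls \code{d = 1 - baf} with \code{q = 1 - p}. The estimator
#' is the least-squares fit through the origin,
#' \code{alphaHat = sum(d * q) / sum(q^2)}, clamped to [0, 1].
#'
#' @param baf numeric vector of B-allele frequencies, or a
#'   \linkS4class{GenotypeMatrix} with \code{BAF} (then one estimate per
#'   sample is returned and the remaining arguments are taken from the
#'   object).
#' @param gt genotype codes matching \code{baf}.
#' @param af population alternate-allele frequencies matching \code{baf}.
#' @param minHomCalls minimum number of usable homozygous calls; below
#'   it the estimate is \code{NA} (undefined), not an error.
#' @return contamination fraction estimate(s) in [0, 1].
#' @export
estimateContamination <- function(baf, gt = NULL, af = NULL,
                                  minHomCalls = 100) {
  if (is(baf, "GenotypeMatrix")) {
    x <- baf
    b <- bafValues(x)
    if (is.null(b)) stop("no BAF values in this dataset")
    g <- genotypes(x)
    p <- mcols(rowRanges(x))$population_af
    return(vapply(seq_len(ncol(x)), function(j)
      estimateContamination(b[, j], g[, j], p,
                            minHomCalls = minHomCalls),
      numeric(1)) |> setNames(colnames(x)))
  }
  ok <- !is.na(baf) & !is.na(gt) & !is.na(af)
  homRef <- ok & gt == "0/0"
  a1 <- substr(gt, 1, 1)
  homAlt <- ok & a1 == substr(gt, 3, 3) & a1 != "0"
  d <- c(baf[homRef], 1 - baf[homAlt])
  q <- c(af[homRef], 1 - af[homAlt])
  if (length(d) < minHomCalls) return(NA_real_)
  min(1, max(0, sum(d * q) / sum(q^2)))
}

#' Replicate call-rate z-scores
#'
#' The z-score of each sample-replicate call rate against the global
#' dataset mean and standard deviation; records at or below the cut-off
#' are flagged as outliers. The default cut-off is -4; -3 is the
#' conservative alternative.
#'
#' @param callRates numeric vector of call rates over all
#'   sample-replicates (at least 3).
#' @param cutoff flag when \code{z <= cutoff} (default -4).
#' @return data.frame with \code{call_rate}, \code{zscore},
#'   \code{z_outlier}.
#' @export
replicateZscores <- function(callRates, cutoff = -4) {
  if (length(callRates) < 3)
    stop("z-scores need at least 3 records")
  s <- sd(callRates)
  z <- if (is.na(s) || s == 0) rep(0, length(callRates))
       else (callRates - mean(callRates)) / s
  data.frame(call_rate = callRates, zscore = z, z_outlier = z <= cutoff)
}

#' Replicate call-rate dispersion
#'
#' For each sample's three replicate call rates: the mean and the
#' population variance (denominator 3) around it. Invariant to
#' replicate order.
#'
#' @param rates numeric vector of 3 call rates, or a 3-column matrix
#'   (one row per sample).
#' @return data.frame with \code{mean} and \code{dispersion}.
#' @export
replicateDispersion <- function(rates) {
  if (is.null(dim(rates))) rates <- matrix(rates, nrow = 1)
  if (ncol(rates) != 3)
    stop("exactly 3 replicate call rates are required per sample")
  m <- rowMeans(rates)
  disp <- rowMeans((rates - m)^2)
  data.frame(mean = m, dispersion = disp,
             row.names = rownames(rates))
}

#' Run per-replicate sample QC
#'
#' Computes, for every sample x replicate: call rate, p10GC, het/hom
#' ratio, contamination estimate and chip placement; then global
#' call-rate z-scores and the QC flags \code{LOW_CALL_RATE} (call rate
#' at or below \code{callRateMin}), \code{CONTAMINATED} (estimate above
#' \code{contaminationMax}), \code{Z_OUTLIER} and \code{EDGE_WELL}
#' (first/last chip row or column).
#'
#' @param replicates list of \linkS4class{GenotypeMatrix} objects (the
#'   array replicates).
#' @param callRateMin,contaminationMax,zCutoff flag thresholds (defaults
#'   0.98, 0.025, -4).
#' @return data.frame, one row per sample x replicate, with a
#'   comma-separated \code{flags} column.
#' @export
sampleQC <- function(replicates, callRateMin = 0.98,
                     contaminationMax = 0.025, zCutoff = -4) {
  recs <- lapply(seq_along(replicates), function(k) {
    x <- replicates[[k]]
    cd <- colData(x)
    hasChip <- all(c("chip_id", "chip_row", "chip_col") %in% colnames(cd))
    data.frame(
      sample_id = colnames(x),
      replicate = k,
      call_rate = callRate(x),
      p10gc = if (!is.null(gcScores(x))) p10gc(x) else NA_real_,
      het_hom_ratio = hetHomRatio(x),
      contamination = if (!is.null(bafValues(x)))
        estimateContamination(x) else NA_real_,
      chip_id = if (hasChip) cd$chip_id else NA_character_,
      chip_row = if (hasChip) cd$chip_row else NA_integer_,
      chip_col = if (hasChip) cd$chip_col else NA_integer_,
      row.names = NULL)
  })
  qc <- do.call(rbind, recs)
  zs <- replicateZscores(qc$call_rate, cutoff = zCutoff)
  qc$zscore <- zs$zscore
  maxRow <- suppressWarnings(max(qc$chip_row, na.rm = TRUE))
  maxCol <- suppressWarnings(max(qc$chip_col, na.rm = TRUE))
  flags <- mapply(function(cr, ct, z, row, col) {
    f <- character()
    if (!is.na(cr) && cr <= callRateMin) f <- c(f, "LOW_CALL_RATE")
    if (!is.na(ct) && ct > contaminationMax) f <- c(f, "CONTAMINATED")
    if (!is.na(z) && z <= zCutoff) f <- c(f, "Z_OUTLIER")
    if (!is.na(row) && (row %in% c(1, maxRow) || col %in% c(1, maxCol)))
      f <- c(f, "EDGE_WELL")
    paste(f, collapse = ",")
  }, qc$call_rate, qc$contamination, qc$zscore, qc$chip_row, qc$chip_col)
  qc$flags <- unname(flags)
  qc
}

#' Replicate summary per sample
#'
#' Combines per-replicate call rates into the per-sample replicate
#' summary: mean, dispersion (population variance), pairwise
#' concordances and the worst replicate by call rate.
#'
#' @param qc data.frame from \code{\link{sampleQC}} (3 replicates per
#'   sample).
#' @param concordance optional data.frame from
#'   \code{\link{pairwiseReplicateConcordance}}.
#' @return data.frame, one row per sample.
#' @export
replicateSummary <- function(qc, concordance = NULL) {
  wide <- reshape(qc[, c("sample_id", "replicate", "call_rate")],
                  idvar = "sample_id", timevar = "replicate",
                  direction = "wide")
  rateCols <- grep("^call_rate\\.", names(wide))
  if (length(rateCols) != 3)
    stop("replicate summary requires exactly 3 replicates per sample")
  rates <- as.matrix(wide[, rateCols])
  dd <- replicateDispersion(rates)
  out <- data.frame(sample_id = wide$sample_id,
                    r1_call_rate = rates[, 1], r2_call_rate = rates[, 2],
                    r3_call_rate = rates[, 3],
                    mean_call_rate = dd$mean, dispersion = dd$dispersion,
                    worst_replicate = max.col(-rates), row.names = NULL)
  if (!is.null(concordance))
    out <- merge(out, concordance, by = "sample_id", sort = FALSE)
  out
}

#' Aggregate QC metrics by chip position
#'
#' Mean, SD, min and max of call rate, p10GC and contamination per
#' (row, column) well position, with an \code{edge_well} indicator for
#' wells on the first/last row or column.
#'
#' @param qc data.frame from \code{\link{sampleQC}} with chip positions.
#' @return data.frame, one row per occupied (row, column).
#' @export
chipPositionSummary <- function(qc) {
  qc <- qc[!is.na(qc$chip_row) & !is.na(qc$chip_col), ]
  maxRow <- max(qc$chip_row); maxCol <- max(qc$chip_col)
  agg <- function(v, f) tapply(v, list(qc$chip_row, qc$chip_col), f)
  grid <- expand.grid(chip_row = sort(unique(qc$chip_row)),
                      chip_col = sort(unique(qc$chip_col)))
  stat <- function(v, f)
    mapply(function(r, co) f(v[qc$chip_row == r & qc$chip_col == co]),
           grid$chip_row, grid$chip_col)
  out <- grid
  for (metric in c("call_rate", "p10gc", "contamination")) {
    v <- qc[[metric]]
    out[[paste0(metric, "_mean")]] <- stat(v, function(x) mean(x, na.rm = TRUE))
    out[[paste0(metric, "_sd")]] <- stat(v, function(x) sd(x[!is.na(x)]))
    out[[paste0(metric, "_min")]] <- stat(v, function(x)
      if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
    out[[paste0(metric, "_max")]] <- stat(v, function(x)
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  }
  out$n <- stat(qc$call_rate, length)
  out$edge_well <- out$chip_row %in% c(1, maxRow) |
    out$chip_col %in% c(1, maxCol)
  out
}

#' Principal-component structure of a genotype matrix
#'
#' Codes genotypes as alternate-allele dosage (0/1/2; the count of
#' non-reference alleles), mean-imputes missing calls per locus, drops
#' all-missing loci with a warning, optionally subsamples loci (default
#' close to 10,000), column-centers and runs an eigendecomposition.
#' Deterministic for a fixed seed.
#'
#' @param x a \linkS4class{GenotypeMatrix} (at least 2 samples).
#' @param nSubsample number of loci to subsample (\code{Inf} for all).
#' @param nPcs number of components returned.
#' @param seed subsampling seed.
#' @param autosomesOnly restrict to autosomes.
#' @return matrix of per-sample PC coordinates (samples x nPcs).
#' @export
pcaStructure <- function(x, nSubsample = 10000, nPcs = 4, seed = 1,
                         autosomesOnly = TRUE) {
  if (ncol(x) < 2) stop("PCA needs at least 2 samples")
  gt <- genotypes(x)
  if (autosomesOnly) gt <- gt[.isAutosome(x), , drop = FALSE]
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  dos <- matrix((a1 != "0") + (a2 != "0"), nrow = nrow(gt))
  dos[is.na(gt)] <- NA_real_
  allMiss <- rowSums(!is.na(dos)) == 0
  if (any(allMiss)) {
    warning(sprintf("%d all-missing loci dropped", sum(allMiss)))
    dos <- dos[!allMiss, , drop = FALSE]
  }
  if (is.finite(nSubsample) && nrow(dos) > nSubsample) {
    set.seed(seed)
    dos <- dos[sort(sample.int(nrow(dos), nSubsample)), , drop = FALSE]
  }
  mu <- rowMeans(dos, na.rm = TRUE)
  idx <- which(is.na(dos))
  if (length(idx)) dos[idx] <- mu[(idx - 1L) %% nrow(dos) + 1L]
  pc <- prcomp(t(dos), center = TRUE, scale. = FALSE,
               rank. = min(nPcs, ncol(x) - 1, nrow(dos)))
  coords <- pc$x
  rownames(coords) <- colnames(x)
  coords
}
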