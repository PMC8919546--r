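## Test-vs-truth genotype-pair classification and performance metrics.
##
## Pair classes: tn (both hom-ref), tp (equal, carrying an alternate
## allele), fp (test carries an alternate, truth hom-ref), fn (test
## hom-ref, truth carries an alternate), x (both carry an alternate but
## differ), na (either call missing). Metrics over the class counts
## a..z: concordance C = (a+c)/(a+b+c+d+z), sensitivity S = a/(a+d),
## specificity P = c/(c+b), PPV = a/(a+b); na pairs never enter a
## denominator.

#' Classify test-vs-truth genotype pairs
#'
#' @param test,truth genotype codes (\code{"0/0"} ... \code{"3/3"},
#'   \code{NA} for a missing call); vectors are classified element-wise.
#' @return character vector over \code{c("tp","fp","tn","fn","x","na")}.
#' @examples
#' classifyPair("0/1", "1/1")  # "x"
#' classifyPair("0/0", "0/0")  # "tn"
#' @export
classifyPair <- function(test, truth) {
  n <- max(length(test), length(truth))
  test <- rep_len(test, n); truth <- rep_len(truth, n)
  out <- character(n)
  isNa <- is.na(test) | is.na(truth)
  refT <- !isNa & test == "0/0"
  refR <- !isNa & truth == "0/0"
  out[isNa] <- "na"
  out[refT & refR] <- "tn"
  out[!isNa & test == truth & !refT] <- "tp"
  out[!refT & refR & !isNa] <- "fp"
  out[refT & !refR] <- "fn"
  out[!isNa & !refT & !refR & test != truth] <- "x"
  out
}

#' Tally pair classes over a comparison scope
#'
#' Classifies every (sample, locus) pair of two harmonized genotype
#' matrices and counts the classes. By default the scope is restricted
#' to autosomal loci passing cluster QC.
#'
#' @param test,truth harmonized \linkS4class{GenotypeMatrix} objects (or
#'   bare genotype-code matrices) with identical dimensions and ordering.
#' @param samples,loci optional subsets (indices or names) restricting
#'   the scope.
#' @param eligibleOnly restrict to cluster-QC-pass loci (default TRUE;
#'   ignored for bare matrices).
#' @param autosomesOnly drop non-autosomal loci (default TRUE; ignored
#'   for bare matrices).
#' @return a \linkS4class{ComparisonTally}.
#' @export
tallyPairs <- function(test, truth, samples = NULL, loci = NULL,
                       eligibleOnly = TRUE, autosomesOnly = TRUE) {
  if (is(test, "GenotypeMatrix") && is(truth, "GenotypeMatrix")) {
    k1 <- paste(as.character(seqnames(rowRanges(test))),
                start(rowRanges(test)))
    k2 <- paste(as.character(seqnames(rowRanges(truth))),
                start(rowRanges(truth)))
    if (!identical(dim(test), dim(truth)) || !identical(k1, k2) ||
        !identical(colnames(test), colnames(truth)))
      stop("matrices are not harmonized; run harmonize() first")
    keep <- rep(TRUE, nrow(test))
    if (eligibleOnly)
      keep <- keep & (mcols(rowRanges(test))$cluster_qc_pass %in% TRUE)
    if (autosomesOnly) keep <- keep & .isAutosome(test)
    tm <- genotypes(test)[keep, , drop = FALSE]
    rm <- genotypes(truth)[keep, , drop = FALSE]
  } else {
    if (!identical(dim(test), dim(truth)))
      stop("matrices are not harmonized; dimensions differ")
    tm <- test; rm <- truth
  }
  if (!is.null(loci)) { tm <- tm[loci, , drop = FALSE]
                        rm <- rm[loci, , drop = FALSE] }
  if (!is.null(samples)) { tm <- tm[, samples, drop = FALSE]
                           rm <- rm[, samples, drop = FALSE] }
  cls <- classifyPair(as.vector(tm), as.vector(rm))
  n <- function(lbl) sum(cls == lbl)
  ComparisonTally(a = n("tp"), b = n("fp"), c = n("tn"), d = n("fn"),
                  z = n("x"), n_na = n("na"))
}

#' Performance metrics from a tally
#'
#' Concordance \code{(a+c)/(a+b+c+d+z)}, sensitivity \code{a/(a+d)},
#' specificity \code{c/(c+b)} and positive predictive value
#' \code{a/(a+b)}. A zero denominator yields \code{NA} (undefined) for
#' that metric; pairs with missing data never enter any formula.
#'
#' @param tally a \linkS4class{ComparisonTally}.
#' @return named numeric: \code{concordance}, \code{sensitivity},
#'   \code{specificity}, \code{ppv}.
#' @export
computeMetrics <- function(tally) {
  stopifnot(is(tally, "ComparisonTally"))
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  with(list(a = tally@a, b = tally@b, c = tally@c, d = tally@d,
            z = tally@z),
       c(concordance = frac(a + c, a + b + c + d + z),
         sensitivity = frac(a, a + d),
         specificity = frac(c, c + b),
         ppv = frac(a, a + b)))
}

#' Pairwise concordance between replicate call sets
#'
#' For each sample, concordance is computed for every pair of replicates
#' (one replicate taken as test, the other as truth; the measure is
#' symmetric in the two).
#'
#' @param replicates list of exactly 3 \linkS4class{GenotypeMatrix}
#'   objects over the same loci and samples.
#' @param eligibleOnly,autosomesOnly scope restrictions as in
#'   \code{\link{tallyPairs}}.
#' @return data.frame with \code{sample_id}, \code{r1r2}, \code{r2r3},
#'   \code{r1r3}.
#' @export
pairwiseReplicateConcordance <- function(replicates, eligibleOnly = TRUE,
                                         autosomesOnly = TRUE) {
  if (length(replicates) != 3)
    stop("exactly 3 replicates are required")
  samples <- colnames(replicates[[1]])
  keep <- rep(TRUE, nrow(replicates[[1]]))
  if (eligibleOnly)
    keep <- keep &
      (mcols(rowRanges(replicates[[1]]))$cluster_qc_pass %in% TRUE)
  if (autosomesOnly) keep <- keep & .isAutosome(replicates[[1]])
  gts <- lapply(replicates, function(x)
    genotypes(x)[keep, , drop = FALSE])
  pairs <- list(r1r2 = c(1, 2), r2r3 = c(2, 3), r1r3 = c(1, 3))
  out <- data.frame(sample_id = samples)
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    cls <- matrix(classifyPair(as.vector(gts[[p[1]]]),
                               as.vector(gts[[p[2]]])),
                  nrow = nrow(gts[[1]]))
    good <- colSums(cls == "tp" | cls == "tn")
    comp <- colSums(cls != "na")
    out[[nm]] <- ifelse(comp > 0, good / comp, NA_real_)
  }
  rownames(out) <- NULL
  out
}

#' Per-assay tallies and metrics
#'
#' One tally / metric row per locus, counted across samples.
#'
#' @inheritParams tallyPairs
#' @return data.frame with \code{assay_id}, the class counts \code{a},
#'   \code{b}, \code{c}, \code{d}, \code{z}, \code{n_na} and the four
#'   metrics.
#' @export
perAssayMetrics <- function(test, truth, samples = NULL,
                            eligibleOnly = TRUE, autosomesOnly = TRUE) {
  keep <- rep(TRUE, nrow(test))
  if (eligibleOnly)
    keep <- keep & (mcols(rowRanges(test))$cluster_qc_pass %in% TRUE)
  if (autosomesOnly) keep <- keep & .isAutosome(test)
  tm <- genotypes(test)[keep, , drop = FALSE]
  rm <- genotypes(truth)[keep, , drop = FALSE]
  if (!is.null(samples)) { tm <- tm[, samples, drop = FALSE]
                           rm <- rm[, samples, drop = FALSE] }
  cls <- matrix(classifyPair(as.vector(tm), as.vector(rm)), nrow = nrow(tm))
  cnt <- function(lbl) rowSums(cls == lbl)
  a <- cnt("tp"); b <- cnt("fp"); cc <- cnt("tn"); d <- cnt("fn")
  z <- cnt("x"); nna <- cnt("na")
  div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  data.frame(assay_id = mcols(rowRanges(test))$assay_id[keep],
             a = a, b = b, c = cc, d = d, z = z, n_na = nna,
             concordance = div(a + cc, a + b + cc + d + z),
             sensitivity = div(a, a + d),
             specificity = div(cc, cc + b),
             ppv = div(a, a + b),
             row.names = NULL)
}

#' Mask low-confidence WGS calls
#'
#' Sets to missing every call below a depth / Phred-quality floor, so
#' that only confidently genotyped WGS calls act as truth (defaults:
#' depth >= 20, quality >= 30).
#'
#' @param x a \linkS4class{GenotypeMatrix} with \code{DP} / \code{GQ}
#'   assays (absent assays impose no constraint).
#' @param minDepth,minQual thresholds.
#' @return the filtered \linkS4class{GenotypeMatrix}.
#' @export
maskLowConfidence <- function(x, minDepth = 20, minQual = 30) {
  gt <- genotypes(x)
  bad <- matrix(FALSE, nrow(gt), ncol(gt))
  if (!is.null(readDepth(x)))
    bad <- bad | (!is.na(readDepth(x)) & readDepth(x) < minDepth)
  if (!is.null(genoQual(x)))
    bad <- bad | (!is.na(genoQual(x)) & genoQual(x) < minQual)
  gt[bad] <- NA_character_
  SummarizedExperiment::assay(x, "GT") <- gt
  x
}

#' Assays adequately covered by a call set
#'
#' Flags assays for which at least \code{minFraction} of samples have a
#' non-missing genotype (default 90\%); assays below the floor are
#' excluded from cross-platform comparisons.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param minFraction minimum fraction of genotyped samples.
#' @return logical vector, one element per locus.
#' @export
assayCoverageOk <- function(x, minFraction = 0.9) {
  rowMeans(!is.na(genotypes(x))) >= minFraction
}

#' Three-way cross-classification of per-assay PPV
#'
#' Cross-classifies assays by whether the array and the WGS call set each
#' attain a positive predictive value of exactly 1 against the same
#' benchmark truth set.
#'
#' @param arrayPpv,wgsPpv per-assay metric tables from
#'   \code{\link{perAssayMetrics}} (same assay set, same truth). Assays
#'   with undefined PPV in either table are dropped.
#' @return list with \code{counts} and \code{fractions}: named vectors
#'   over \code{both_1}, \code{array_only}, \code{wgs_only},
#'   \code{neither}, plus \code{n} assays compared.
#' @export
threeWayPpv <- function(arrayPpv, wgsPpv) {
  if (!setequal(arrayPpv$assay_id, wgsPpv$assay_id))
    stop("assay sets differ between the two PPV tables")
  m <- match(arrayPpv$assay_id, wgsPpv$assay_id)
  g <- arrayPpv$ppv
  w <- wgsPpv$ppv[m]
  ok <- !is.na(g) & !is.na(w)
  g <- g[ok]; w <- w[ok]
  counts <- c(both_1 = sum(g == 1 & w == 1),
              array_only = sum(g == 1 & w < 1),
              wgs_only = sum(g < 1 & w == 1),
              neither = sum(g < 1 & w < 1))
  list(counts = counts, fractions = counts / max(1, sum(counts)),
       n = sum(counts))
}
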