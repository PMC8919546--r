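#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start width findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowRanges colData colData<-
#' @importFrom stats prcomp quantile rbeta rbinom rnbinom rnorm runif sd
#'   var kmeans setNames reshape
#' @importFrom utils read.table write.table
NULL

## The 10 unordered genotype codes over a reference allele (index 0) and up
## to three alternate alleles (indices 1-3), plus NA for a no-call.
.GT_CODES <- c("0/0", "0/1", "0/2", "0/3", "1/1", "1/2", "1/3",
               "2/2", "2/3", "3/3")

.AUTOSOMES <- as.character(1:22)

#' GenotypeMatrix: samples-by-loci unphased genotype calls
#'
#' A \code{GenotypeMatrix} is a
#' \linkS4class{RangedSummarizedExperiment} whose rows are assayed loci
#' (a \code{GRanges} carrying \code{assay_id}, \code{ref}, \code{alt},
#' \code{cluster_qc_pass} and optionally \code{population_af} metadata
#' columns) and whose columns are samples. The mandatory \code{"GT"} assay
#' holds unordered genotype codes (\code{"0/0"}, \code{"0/1"}, ...,
#' \code{"3/3"}; \code{NA} for a no-call). Optional assays carry per-call
#' GenCall-like quality scores (\code{"GC"}), B-allele frequencies
#' (\code{"BAF"}), read depth (\code{"DP"}) and Phred-scaled genotype
#' quality (\code{"GQ"}). Chip placement (\code{chip_id}, \code{chip_row},
#' \code{chip_col}) lives in \code{colData}; the replicate identifier in
#' \code{metadata(x)$replicate_id}.
#'
#' @aliases GenotypeMatrix-class
#' @export
setClass("GenotypeMatrix",
         contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (!("GT" %in% assayNames(object)))
    msg <- c(msg, "assay 'GT' is required")
  else {
    gt <- assay(object, "GT")
    if (!is.character(gt))
      msg <- c(msg, "assay 'GT' must be a character matrix")
    else {
      bad <- !is.na(gt) & !(gt %in% .GT_CODES)
      if (any(bad))
        msg <- c(msg, sprintf("invalid genotype code(s): %s",
                              paste(unique(gt[bad])[1:min(3, sum(bad))],
                                    collapse = ", ")))
    }
  }
  need <- c("assay_id", "ref", "alt", "cluster_qc_pass")
  miss <- setdiff(need, colnames(mcols(rowRanges(object))))
  if (length(miss))
    msg <- c(msg, sprintf("rowRanges lack metadata column(s): %s",
                          paste(miss, collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique within a replicate")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param gt character matrix of genotype codes, loci in rows, samples in
#'   columns; \code{NA} marks a no-call.
#' @param loci \code{GRanges} of assayed positions (1-based), one per row of
#'   \code{gt}, with metadata columns \code{assay_id}, \code{ref},
#'   \code{alt} (comma-joined for multi-allelic assays),
#'   \code{cluster_qc_pass} and optionally \code{population_af}.
#' @param sampleData \code{DataFrame}/\code{data.frame} of per-sample
#'   metadata (row names are sample ids); typically \code{chip_id},
#'   \code{chip_row}, \code{chip_col}.
#' @param gc,baf,depth,qual optional numeric matrices with the dimensions of
#'   \code{gt}: GenCall-like score, B-allele frequency, read depth,
#'   Phred-scaled genotype quality.
#' @param replicateId replicate label stored in the object metadata.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(gt, loci, sampleData = NULL,
                           gc = NULL, baf = NULL, depth = NULL, qual = NULL,
                           replicateId = NA_character_) {
  if (is.null(colnames(gt)))
    stop("'gt' must have sample ids as column names")
  aid <- mcols(loci)$assay_id
  if (is.null(rownames(gt)) && !is.null(aid)) rownames(gt) <- aid
  if (!is.null(aid)) names(loci) <- aid
  assays <- list(GT = gt)
  if (!is.null(gc))    assays$GC  <- gc
  if (!is.null(baf))   assays$BAF <- baf
  if (!is.null(depth)) assays$DP  <- depth
  if (!is.null(qual))  assays$GQ  <- qual
  if (is.null(sampleData))
    sampleData <- DataFrame(row.names = colnames(gt))
  se <- SummarizedExperiment(assays = assays, rowRanges = loci,
                             colData = as(sampleData, "DataFrame"))
  out <- new("GenotypeMatrix", se)
  metadata(out)$replicate_id <- replicateId
  out
}

setMethod("show", "GenotypeMatrix", function(object) {
  gt <- assay(object, "GT")
  cat(sprintf("GenotypeMatrix: %d loci x %d samples (replicate %s)\n",
              nrow(object), ncol(object),
              as.character(metadata(object)$replicate_id)))
  cat(sprintf("  assays: %s\n", paste(assayNames(object), collapse = ", ")))
  cat(sprintf("  no-call fraction: %.4g\n", mean(is.na(gt))))
  invisible(NULL)
})

#' @describeIn GenotypeMatrix-accessors genotype code matrix (loci x samples)
#' @export
genotypes <- function(x) assay(x, "GT")

#' Accessors for GenotypeMatrix per-call assays
#'
#' \code{genotypes}, \code{gcScores}, \code{bafValues}, \code{readDepth}
#' and \code{genoQual} return the corresponding per-call matrix (or
#' \code{NULL} when the assay is absent); \code{replicateId} the replicate
#' label; \code{lociRanges} the row \code{GRanges}.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @name GenotypeMatrix-accessors
NULL

.assayOrNull <- function(x, name)
  if (name %in% assayNames(x)) assay(x, name) else NULL

#' @rdname GenotypeMatrix-accessors
#' @export
gcScores <- function(x) .assayOrNull(x, "GC")

#' @rdname GenotypeMatrix-accessors
#' @export
bafValues <- function(x) .assayOrNull(x, "BAF")

#' @rdname GenotypeMatrix-accessors
#' @export
readDepth <- function(x) .assayOrNull(x, "DP")

#' @rdname GenotypeMatrix-accessors
#' @export
genoQual <- function(x) .assayOrNull(x, "GQ")

#' @rdname GenotypeMatrix-accessors
#' @export
replicateId <- function(x) metadata(x)$replicate_id

#' @rdname GenotypeMatrix-accessors
#' @export
lociRanges <- function(x) rowRanges(x)

## logical index of autosomal rows
.isAutosome <- function(x) {
  chr <- as.character(seqnames(rowRanges(x)))
  sub("^chr", "", chr) %in% .AUTOSOMES
}

#' ComparisonTally: genotype-pair classification counts
#'
#' Counts of the six pair classes from a test-vs-truth comparison:
#' \code{a} (true positive), \code{b} (false positive), \code{c} (true
#' negative), \code{d} (false negative), \code{z} (other discordant, both
#' genotypes carry an alternate allele but differ) and \code{n_na} (pairs
#' with missing data, which never enter any metric).
#'
#' @aliases ComparisonTally-class
#' @export
setClass("ComparisonTally",
         representation(a = "numeric", b = "numeric", c = "numeric",
                        d = "numeric", z = "numeric", n_na = "numeric"))

setValidity("ComparisonTally", function(object) {
  v <- c(object@a, object@b, object@c, object@d, object@z, object@n_na)
  if (any(v < 0)) "counts must be non-negative" else TRUE
})

#' @param a,b,c,d,z,n_na class counts (tp, fp, tn, fn, other-discordant,
#'   no-data).
#' @rdname ComparisonTally-class
#' @export
ComparisonTally <- function(a = 0, b = 0, c = 0, d = 0, z = 0, n_na = 0)
  new("ComparisonTally", a = a, b = b, c = c, d = d, z = z, n_na = n_na)

#' @param x a \code{ComparisonTally}.
#' @return \code{tallyCounts}: named numeric vector
#'   \code{c(a, b, c, d, z, n_na)}.
#' @rdname ComparisonTally-class
#' @export
tallyCounts <- function(x)
  c(a = x@a, b = x@b, c = x@c, d = x@d, z = x@z, n_na = x@n_na)

setMethod("show", "ComparisonTally", function(object) {
  cat("ComparisonTally\n")
  print(tallyCounts(object))
  invisible(NULL)
})
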