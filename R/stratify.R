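## Assay stratification: variant type, transition/transversion class,
## 13 allele-frequency bins, low-complexity-region intersection, panel
## selection chain, and per-stratum metric aggregation.

.AF_EDGES <- c(0, 0.001, 0.01, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50,
               0.60, 0.70, 0.80, 0.90, 1)
.AF_LABELS <- c("[0-0.1%]", "(0.1-1%]", "(1-5%]", "(5-10%]", "(10-20%]",
                "(20-30%]", "(30-40%]", "(40-50%]", "(50-60%]",
                "(60-70%]", "(70-80%]", "(80-90%]", "(90-100%]")

#' Classify the variant type of an assay
#'
#' MAV (multi-allelic) when more than one alternate allele; otherwise
#' SNV when ref and alt are single bases, INS when the alternate is
#' longer than the reference, DEL when shorter. Equal-length multi-base
#' substitutions (MNVs) do not fit any class: they are labeled
#' \code{"MNV"} with a warning and are meant to be excluded.
#'
#' @param ref reference allele string(s).
#' @param alt alternate allele string(s); multiple alternates
#'   comma-joined.
#' @return character vector over
#'   \code{c("SNV","INS","DEL","MAV","MNV")}.
#' @export
classifyVariantType <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  nAlt <- lengths(strsplit(alt, ",", fixed = TRUE))
  firstAlt <- sub(",.*", "", alt)
  out <- ifelse(nAlt > 1, "MAV",
         ifelse(nchar(ref) == 1 & nchar(firstAlt) == 1, "SNV",
         ifelse(nchar(firstAlt) > nchar(ref), "INS",
         ifelse(nchar(firstAlt) < nchar(ref), "DEL", "MNV"))))
  if (any(out == "MNV"))
    warning(sprintf("%d equal-length multi-base substitution(s) labeled MNV and excluded from typed strata",
                    sum(out == "MNV")))
  out
}

#' Classify a single-nucleotide change
#'
#' Transition when both alleles are purines (A, G) or both pyrimidines
#' (C, T); transversion otherwise. Transversions between complementary
#' bases (A>T, T>A, C>G, G>C) are additionally flagged.
#'
#' @param ref,alt single bases, \code{ref != alt}.
#' @return data.frame with \code{change_class} and
#'   \code{complementary_tv}.
#' @export
classifySnvChange <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- toupper(rep_len(ref, n)); alt <- toupper(rep_len(alt, n))
  if (any(!ref %in% .BASES) || any(!alt %in% .BASES))
    stop("alleles must be single bases over A, C, G, T")
  if (any(ref == alt)) stop("ref and alt must differ")
  purine <- c("A", "G")
  ts <- (ref %in% purine) == (alt %in% purine)
  data.frame(change_class = ifelse(ts, "transition", "transversion"),
             complementary_tv = !ts & alt == .COMPL[ref])
}

#' Bin an alternate allele frequency
#'
#' Thirteen bins on the percent scale: a closed first bin [0-0.1\%] and
#' upper-inclusive half-open bins (0.1-1\%], (1-5\%], (5-10\%] and then
#' decades up to (90-100\%]. Every frequency in [0, 1] maps to exactly
#' one bin.
#'
#' @param af alternate-allele frequency fraction(s) in [0, 1].
#' @return factor with the 13 bin labels.
#' @export
afBin <- function(af) {
  if (any(is.na(af)) || any(af < 0 | af > 1))
    stop("allele frequencies must lie in [0, 1]")
  cut(af, breaks = .AF_EDGES, labels = .AF_LABELS,
      include.lowest = TRUE, right = TRUE)
}

#' Flag loci inside low-complexity regions
#'
#' Intersects 1-based locus positions with one BED file (0-based
#' half-open) per low-complexity class; a locus at position p is flagged
#' for a class iff p-1 falls inside one of its intervals. Classes are
#' independent and may overlap.
#'
#' @param loci \code{GRanges} of 1-based positions (width-1 ranges), or
#'   a \linkS4class{GenotypeMatrix}.
#' @param bedFiles named character vector/list of BED paths, one per
#'   class.
#' @return logical matrix, loci x classes.
#' @export
intersectLcr <- function(loci, bedFiles) {
  if (is(loci, "GenotypeMatrix")) loci <- rowRanges(loci)
  out <- matrix(FALSE, length(loci), length(bedFiles),
                dimnames = list(NULL, names(bedFiles)))
  for (cls in names(bedFiles)) {
    bed <- rtracklayer::import(bedFiles[[cls]], format = "BED")
    if (length(bed))
      out[, cls] <- GenomicRanges::countOverlaps(loci, bed,
                                                 ignore.strand = TRUE) > 0
  }
  out
}

#' Build the per-assay annotation table
#'
#' Derives every stratum label for each assay: variant type,
#' transition/transversion class with the complementary-transversion
#' flag, allele-frequency bin, low-complexity flags (from BED files when
#' given, else from flags already on the object) and panel flags.
#'
#' @param truth a \linkS4class{GenotypeMatrix} whose row metadata carry
#'   \code{population_af} (and optionally panel / LCR flags).
#' @param lcrBeds optional named BED paths; when supplied they override
#'   any flags on the object.
#' @return data.frame, one row per assay.
#' @export
annotateAssays <- function(truth, lcrBeds = NULL) {
  loci <- rowRanges(truth)
  md <- mcols(loci)
  vt <- classifyVariantType(md$ref, md$alt)
  chg <- rep(NA_character_, length(loci))
  ctv <- rep(FALSE, length(loci))
  isSnv <- vt == "SNV"
  if (any(isSnv)) {
    cc <- classifySnvChange(md$ref[isSnv], md$alt[isSnv])
    chg[isSnv] <- cc$change_class
    ctv[isSnv] <- cc$complementary_tv
  }
  af <- md$population_af
  bin <- rep(NA_character_, length(loci))
  okAf <- !is.na(af)
  bin[okAf] <- as.character(afBin(af[okAf]))
  lcrCls <- c("SimpleRepeat", "Microsatellite", "RepeatMasker")
  if (!is.null(lcrBeds)) {
    lcr <- intersectLcr(loci, lcrBeds)
    lcrDf <- as.data.frame(lcr)
    names(lcrDf) <- paste0("lcr_", colnames(lcr))
  } else {
    lcrDf <- as.data.frame(lapply(paste0("lcr_", lcrCls), function(nm)
      if (!is.null(md[[nm]])) md[[nm]] else rep(FALSE, length(loci))))
    names(lcrDf) <- paste0("lcr_", lcrCls)
  }
  flag <- function(nm)
    if (!is.null(md[[nm]])) md[[nm]] else rep(FALSE, length(loci))
  data.frame(assay_id = md$assay_id,
             chrom = as.character(seqnames(loci)), pos = start(loci),
             ref = md$ref, alt = md$alt,
             variant_type = vt, change_class = chg,
             complementary_tv = ctv,
             population_af = af, af_bin = bin, lcrDf,
             in_transcript_window = flag("in_transcript_window"),
             clinvar_path = flag("clinvar_path"),
             hgmd = flag("hgmd"), curated_mvl = flag("curated_mvl"),
             cluster_qc_pass = md$cluster_qc_pass %in% TRUE,
             any_lcr = Reduce(`|`, lcrDf),
             row.names = NULL)
}

#' Aggregate per-assay metrics by stratum
#'
#' Per stratum level: number of assays, mean and quartiles of each
#' metric, and the fractions of assays with PPV exactly 1 and below 1.
#'
#' @param perAssay per-assay table from \code{\link{perAssayMetrics}}.
#' @param annotations table from \code{\link{annotateAssays}}.
#' @param key annotation column to stratify on (e.g.
#'   \code{"variant_type"}, \code{"change_class"}, \code{"af_bin"},
#'   \code{"any_lcr"}).
#' @return data.frame, one row per stratum level.
#' @export
stratifiedMetrics <- function(perAssay, annotations, key) {
  if (!key %in% names(annotations))
    stop("unknown stratum key: ", key)
  m <- match(perAssay$assay_id, annotations$assay_id)
  if (any(is.na(m)))
    stop("annotations do not cover all assays")
  stratum <- annotations[[key]][m]
  lv <- if (key == "af_bin") .AF_LABELS[.AF_LABELS %in% stratum]
        else sort(unique(stratum[!is.na(stratum)]))
  rows <- lapply(lv, function(s) {
    i <- which(!is.na(stratum) & stratum == s)
    row <- data.frame(stratum = as.character(s), n_assays = length(i))
    for (metric in c("concordance", "sensitivity", "specificity", "ppv")) {
      v <- perAssay[[metric]][i]
      v <- v[!is.na(v)]
      q <- if (length(v)) quantile(v, c(0.25, 0.5, 0.75)) else rep(NA_real_, 3)
      row[[paste0(metric, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0(metric, "_q1")]] <- unname(q[1])
      row[[paste0(metric, "_median")]] <- unname(q[2])
      row[[paste0(metric, "_q3")]] <- unname(q[3])
    }
    ppv <- perAssay$ppv[i]
    defined <- sum(!is.na(ppv))
    row$frac_ppv_1 <- if (defined) sum(ppv == 1, na.rm = TRUE) / defined
                      else NA_real_
    row$frac_ppv_lt1 <- if (defined) sum(ppv < 1, na.rm = TRUE) / defined
                        else NA_real_
    row
  })
  do.call(rbind, rows)
}

#' Stepwise selection of the actionable-panel assays
#'
#' Sequential filter chain for assays targeting medically actionable
#' predispositions: (1) position within the transcript window
#' (transcript start - flank to end + flank); (2) a
#' pathogenic/likely-pathogenic ClinVar classification; (3) an HGMD
#' record; (4) curation into the managed variant list. Each step records
#' the surviving assay count; counts are non-increasing by construction.
#'
#' @param annotations table from \code{\link{annotateAssays}} (needs
#'   \code{chrom}, \code{pos} and the panel flag columns).
#' @param transcripts data.frame with \code{gene}, \code{chrom},
#'   \code{tx_start}, \code{tx_end} (1-based inclusive).
#' @param flank window extension in bases (default 1000).
#' @return list with \code{report} (data.frame of \code{step},
#'   \code{n_assays}) and \code{assays} (surviving assay ids).
#' @export
selectMapPanel <- function(annotations, transcripts, flank = 1000) {
  if (is.null(transcripts) || nrow(transcripts) == 0)
    stop("empty transcript table")
  inWin <- rep(FALSE, nrow(annotations))
  for (g in seq_len(nrow(transcripts))) {
    inWin <- inWin | (annotations$chrom == transcripts$chrom[g] &
                      annotations$pos >= transcripts$tx_start[g] - flank &
                      annotations$pos <= transcripts$tx_end[g] + flank)
  }
  s1 <- inWin
  s2 <- s1 & annotations$clinvar_path %in% TRUE
  s3 <- s2 & annotations$hgmd %in% TRUE
  s4 <- s3 & annotations$curated_mvl %in% TRUE
  report <- data.frame(
    step = c("transcript_window", "clinvar_pathogenic", "hgmd",
             "curated_mvl"),
    n_assays = c(sum(s1), sum(s2), sum(s3), sum(s4)))
  list(report = report, assays = annotations$assay_id[s4])
}

#' Percentage with half-away-from-zero rounding
#'
#' \code{100 * numerator / denominator}, rounded half away from zero to
#' \code{decimals} places (the convention of printed summary tables,
#' unlike banker's rounding). A zero denominator yields \code{NA}.
#'
#' @param numerator,denominator counts.
#' @param decimals decimal places (default 0).
#' @return numeric percentage(s).
#' @examples
#' percentSummary(610771, 661126)  # 92
#' @export
percentSummary <- function(numerator, denominator, decimals = 0) {
  out <- rep(NA_real_, max(length(numerator), length(denominator)))
  numerator <- rep_len(numerator, length(out))
  denominator <- rep_len(denominator, length(out))
  ok <- denominator > 0
  x <- 100 * numerator[ok] / denominator[ok]
  f <- 10^decimals
  out[ok] <- sign(x) * floor(abs(x) * f + 0.5) / f
  out
}
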