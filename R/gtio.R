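## Genotype encoding, VCF read/write, and cross-dataset locus harmonization.

#' Encode an allele pair as an unordered genotype code
#'
#' Alleles matching the reference are index 0, the first / second / third
#' alternate alleles indices 1 / 2 / 3; a genotype is the unordered pair
#' of indices (lower index first), giving ten possible genotypes for a
#' reference plus up to three alternates.
#'
#' @param allele1,allele2 allele strings.
#' @param ref reference allele string.
#' @param alts character vector of 1-3 alternate allele strings.
#' @return genotype code such as \code{"0/1"}.
#' @examples
#' encodeGenotype("G", "A", ref = "A", alts = "G")  # "0/1"
#' @export
encodeGenotype <- function(allele1, allele2, ref, alts) {
  if (length(alts) < 1 || length(alts) > 3)
    stop("a locus carries 1 to 3 alternate alleles")
  alleles <- c(ref, alts)
  i <- match(allele1, alleles) - 1L
  j <- match(allele2, alleles) - 1L
  if (is.na(i) || is.na(j))
    stop(sprintf("allele '%s' not in the locus allele set {%s}",
                 if (is.na(i)) allele1 else allele2,
                 paste(alleles, collapse = ", ")))
  paste(min(i, j), max(i, j), sep = "/")
}

## "0|1", "1/0" -> "0/1"; "./.", ".", ".|." -> NA
.normalizeGtString <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  gt[gt %in% c(".", "./.", ".|.")] <- NA_character_
  miss <- grepl(".", gt, fixed = TRUE)
  gt[miss] <- NA_character_
  a <- sub("/.*", "", gt)
  b <- sub(".*/", "", gt)
  ok <- !is.na(gt)
  out <- gt
  out[ok] <- paste(pmin(a[ok], b[ok]), pmax(a[ok], b[ok]), sep = "/")
  out
}

#' Read a genotype VCF into a GenotypeMatrix
#'
#' Wraps \code{VariantAnnotation::readVcf}. Each record becomes one locus;
#' \code{GT} is parsed to the unordered code space (phased separators are
#' treated as unphased; \code{"./."} becomes a missing call); per-call
#' \code{GC}, \code{BAF}, \code{DP} and \code{GQ} FORMAT fields and the
#' \code{AF}, \code{AID} and \code{CQC} INFO fields are lifted when
#' present. Records with more than three alternate alleles are skipped
#' with a warning.
#'
#' @param path VCF file.
#' @param sampleSheet optional data.frame with columns \code{sample_id},
#'   \code{replicate}, \code{chip_id}, \code{chip_row}, \code{chip_col};
#'   rows matching \code{replicateId} populate \code{colData}.
#' @param replicateId replicate label to store (and to select sample-sheet
#'   rows).
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
readGenotypeVcf <- function(path, sampleSheet = NULL,
                            replicateId = NA_character_) {
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  altL <- VariantAnnotation::alt(vcf)
  nAlt <- lengths(altL)
  keep <- nAlt >= 1 & nAlt <= 3
  if (any(!keep)) {
    warning(sprintf("%d record(s) with >3 (or 0) alternate alleles skipped",
                    sum(!keep)))
    vcf <- vcf[keep]
    altL <- altL[keep]
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  loci <- GRanges(seqnames(rr), IRanges(start(rr), width = 1))
  info <- VariantAnnotation::info(vcf)
  afInfo <- if ("AF" %in% colnames(info))
    vapply(info$AF, function(x) sum(as.numeric(x)), numeric(1))
  else rep(NA_real_, length(loci))
  mcols(loci) <- DataFrame(
    assay_id = if ("AID" %in% colnames(info)) as.character(info$AID)
               else names(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = vapply(altL, function(x) paste(as.character(x), collapse = ","),
                 character(1)),
    cluster_qc_pass = if ("CQC" %in% colnames(info)) info$CQC > 0
                      else rep(TRUE, length(loci)),
    population_af = afInfo)
  g <- VariantAnnotation::geno(vcf)
  gt <- matrix(.normalizeGtString(g$GT), nrow = nrow(g$GT),
               dimnames = dimnames(g$GT))
  num <- function(nm) {
    if (!(nm %in% names(g))) return(NULL)
    m <- g[[nm]]
    storage.mode(m) <- "double"
    m
  }
  cd <- NULL
  if (!is.null(sampleSheet)) {
    sh <- sampleSheet
    if ("replicate" %in% names(sh) && !is.na(replicateId)) {
      repNum <- sub("^rep", "", as.character(replicateId))
      sh <- sh[as.character(sh$replicate) %in%
                 c(repNum, as.character(replicateId)), , drop = FALSE]
    }
    m <- match(colnames(gt), sh$sample_id)
    cd <- DataFrame(chip_id = sh$chip_id[m], chip_row = sh$chip_row[m],
                    chip_col = sh$chip_col[m], row.names = colnames(gt))
  }
  GenotypeMatrix(gt, loci, sampleData = cd,
                 gc = num("GC"), baf = num("BAF"), depth = num("DP"),
                 qual = num("GQ"), replicateId = replicateId)
}

.fmtNum <- function(x, digits = 4) {
  out <- ifelse(is.na(x), ".",
                sub("\\.?0+$", "", sprintf(paste0("%.", digits, "f"), x)))
  out
}

#' Write a GenotypeMatrix as VCF
#'
#' Emits a VCF v4.2 file with unphased genotypes (missing calls written
#' as \code{"./."}), per-call \code{GC} / \code{BAF} / \code{DP} /
#' \code{GQ} FORMAT fields for the assays the object carries, and the
#' population allele frequency (\code{AF}), assay identifier (\code{AID})
#' and cluster-QC pass flag (\code{CQC}) as INFO fields. Output is
#' deterministic for identical input.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGenotypeVcf <- function(x, path) {
  loci <- rowRanges(x)
  md <- mcols(loci)
  gt <- genotypes(x)
  fmt <- c("GT",
           if (!is.null(gcScores(x))) "GC",
           if (!is.null(bafValues(x))) "BAF",
           if (!is.null(readDepth(x))) "DP",
           if (!is.null(genoQual(x))) "GQ")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=arrayvalid",
           "##INFO=<ID=AID,Number=1,Type=String,Description=\"Assay identifier\">",
           "##INFO=<ID=CQC,Number=1,Type=Integer,Description=\"Cluster QC pass (1) or fail (0)\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Population alternate allele frequency (total over alternates)\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           if ("GC" %in% fmt) "##FORMAT=<ID=GC,Number=1,Type=Float,Description=\"GenCall-like quality score\">",
           if ("BAF" %in% fmt) "##FORMAT=<ID=BAF,Number=1,Type=Float,Description=\"B allele frequency\">",
           if ("DP" %in% fmt) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           if ("GQ" %in% fmt) "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Phred-scaled genotype quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
  af <- md$population_af
  if (is.null(af)) af <- rep(NA_real_, length(loci))
  infoCol <- paste0("AID=", md$assay_id,
                    ";CQC=", as.integer(md$cluster_qc_pass),
                    ifelse(is.na(af), "", paste0(";AF=", .fmtNum(af, 6))))
  cell <- ifelse(is.na(gt), "./.", gt)
  addField <- function(cell, m, digits, integer = FALSE) {
    s <- if (integer) ifelse(is.na(m), ".", format(m, trim = TRUE,
                                                   scientific = FALSE))
         else .fmtNum(m, digits)
    paste(cell, s, sep = ":")
  }
  if ("GC" %in% fmt)  cell <- addField(cell, gcScores(x), 4)
  if ("BAF" %in% fmt) cell <- addField(cell, bafValues(x), 4)
  if ("DP" %in% fmt)  cell <- addField(cell, readDepth(x), 0, integer = TRUE)
  if ("GQ" %in% fmt)  cell <- addField(cell, genoQual(x), 0, integer = TRUE)
  body <- paste(as.character(seqnames(loci)), start(loci), md$assay_id,
                md$ref, md$alt, ".", ".", infoCol,
                paste(fmt, collapse = ":"),
                apply(matrix(cell, nrow = nrow(gt)), 1, paste,
                      collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Harmonize genotype datasets onto a shared locus index
#'
#' Loci are matched across datasets on (chromosome, position, reference
#' allele, alternate-allele set). Datasets whose alternate alleles are
#' listed in a different order are remapped to the first dataset's
#' indexing (genotype codes are rewritten through the allele
#' permutation). Loci at the same position with conflicting reference
#' alleles, or with different allele sets, are excluded and recorded;
#' loci absent from any dataset are excluded and counted. Samples are
#' matched by id. Harmonization is idempotent.
#'
#' @param datasets list of at least two \linkS4class{GenotypeMatrix}
#'   objects.
#' @return list with \code{matrices} (the harmonized
#'   \code{GenotypeMatrix} objects, common loci and samples, first
#'   dataset's allele indexing), \code{excluded} (data.frame of excluded
#'   loci with reasons) and \code{n_common} loci.
#' @export
harmonize <- function(datasets) {
  if (length(datasets) < 2)
    stop("harmonization needs at least two datasets")
  keyOf <- function(x) {
    loci <- rowRanges(x)
    paste(as.character(seqnames(loci)), start(loci), sep = ":")
  }
  keys <- lapply(datasets, keyOf)
  common <- Reduce(intersect, keys)
  excl <- list()
  ref1 <- alt1 <- NULL
  ## locus-level consistency against dataset 1
  i1 <- match(common, keys[[1]])
  md1 <- mcols(rowRanges(datasets[[1]]))[i1, ]
  keep <- rep(TRUE, length(common))
  for (k in seq_along(datasets)[-1]) {
    ik <- match(common, keys[[k]])
    mdk <- mcols(rowRanges(datasets[[k]]))[ik, ]
    refConflict <- mdk$ref != md1$ref
    set1 <- lapply(strsplit(md1$alt, ",", fixed = TRUE), sort)
    setk <- lapply(strsplit(mdk$alt, ",", fixed = TRUE), sort)
    altConflict <- !mapply(identical, set1, setk)
    if (any(refConflict))
      excl$ref <- rbind(excl$ref,
                        data.frame(key = common[refConflict],
                                   reason = "ref_conflict"))
    if (any(altConflict & !refConflict))
      excl$alt <- rbind(excl$alt,
                        data.frame(key = common[altConflict & !refConflict],
                                   reason = "alt_set_mismatch"))
    keep <- keep & !refConflict & !altConflict
  }
  common <- common[keep]
  md1 <- md1[keep, ]
  samples <- Reduce(intersect, lapply(datasets, colnames))
  if (!length(samples)) stop("no shared samples across datasets")

  out <- vector("list", length(datasets))
  for (k in seq_along(datasets)) {
    x <- datasets[[k]][match(common, keys[[k]]), samples]
    if (k > 1) {
      altk <- strsplit(mcols(rowRanges(x))$alt, ",", fixed = TRUE)
      alt1 <- strsplit(md1$alt, ",", fixed = TRUE)
      differs <- which(!mapply(identical, altk, alt1))
      if (length(differs)) {
        gt <- assay(x, "GT")
        for (i in differs) {
          map <- c(0L, match(altk[[i]], alt1[[i]]))  # old idx -> new idx
          g <- gt[i, ]
          ok <- !is.na(g)
          a <- map[as.integer(substr(g[ok], 1, 1)) + 1L]
          b <- map[as.integer(substr(g[ok], 3, 3)) + 1L]
          gt[i, ok] <- .codeFromAlleles(a, b)
        }
        SummarizedExperiment::assay(x, "GT") <- gt
        rr <- rowRanges(x)
        mcols(rr)$alt <- md1$alt
        SummarizedExperiment::rowRanges(x) <- rr
      }
    }
    out[[k]] <- x
  }
  names(out) <- names(datasets)
  excluded <- do.call(rbind, excl)
  if (is.null(excluded))
    excluded <- data.frame(key = character(), reason = character())
  excluded <- unique(excluded)
  list(matrices = out, excluded = excluded, n_common = length(common))
}
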