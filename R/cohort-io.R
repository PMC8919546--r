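## Serialize a simulated cohort to the pipeline's input formats (VCF, BED,
## TSV) and read it back.

.writeTsv <- function(df, path)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Write a cohort to standard file formats
#'
#' Emits, under \code{outDir}: one VCF per array replicate
#' (\code{array_rep<k>.vcf}, with GT/GC/BAF), a truth VCF
#' (\code{truth.vcf}), a WGS VCF (\code{wgs.vcf}, with GT/DP/GQ), an
#' assay-annotation TSV, one BED file (0-based half-open) per
#' low-complexity class, a transcript-window TSV and a sample sheet with
#' chip placements. Files round-trip losslessly through
#' \code{\link{readCohort}}.
#'
#' @param truth,arrayReplicates,wgs objects from
#'   \code{\link{simulateCohort}} (the array element is the list of
#'   replicate matrices).
#' @param outDir output directory, created if needed.
#' @return named character vector of written paths, invisibly.
#' @export
writeCohort <- function(truth, arrayReplicates, wgs, outDir) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  paths <- c(truth = file.path(outDir, "truth.vcf"),
             wgs = file.path(outDir, "wgs.vcf"))
  writeGenotypeVcf(truth, paths["truth"])
  writeGenotypeVcf(wgs, paths["wgs"])
  sheets <- list()
  for (k in seq_along(arrayReplicates)) {
    p <- file.path(outDir, sprintf("array_rep%d.vcf", k))
    paths[sprintf("array_rep%d", k)] <- p
    writeGenotypeVcf(arrayReplicates[[k]], p)
    cd <- colData(arrayReplicates[[k]])
    sheets[[k]] <- data.frame(sample_id = rownames(cd), replicate = k,
                              chip_id = cd$chip_id, chip_row = cd$chip_row,
                              chip_col = cd$chip_col)
  }
  paths["sample_sheet"] <- file.path(outDir, "sample_sheet.tsv")
  .writeTsv(do.call(rbind, sheets), paths["sample_sheet"])

  md <- as.data.frame(mcols(rowRanges(truth)))
  loci <- rowRanges(truth)
  ann <- cbind(data.frame(chrom = as.character(seqnames(loci)),
                          pos = start(loci)), md)
  paths["annotations"] <- file.path(outDir, "annotations.tsv")
  .writeTsv(ann, paths["annotations"])

  tr <- metadata(truth)$transcripts
  if (!is.null(tr)) {
    paths["transcripts"] <- file.path(outDir, "transcripts.tsv")
    .writeTsv(tr, paths["transcripts"])
  }

  ## one 0-based half-open interval per flagged locus
  for (cls in c("SimpleRepeat", "Microsatellite", "RepeatMasker")) {
    flag <- md[[paste0("lcr_", cls)]]
    p <- file.path(outDir, sprintf("lcr_%s.bed", cls))
    paths[paste0("lcr_", cls)] <- p
    i <- which(flag %in% TRUE)
    bed <- data.frame(chrom = as.character(seqnames(loci))[i],
                      start = start(loci)[i] - 1L, end = start(loci)[i])
    writeLines(if (nrow(bed)) paste(bed$chrom, bed$start, bed$end,
                                    sep = "\t") else character(0), p)
  }
  invisible(paths)
}

#' Read a cohort written by writeCohort
#'
#' @param dir directory produced by \code{\link{writeCohort}}.
#' @return list with \code{truth}, \code{array} (list of replicate
#'   \linkS4class{GenotypeMatrix}), \code{wgs}, \code{annotations},
#'   \code{transcripts}, \code{sampleSheet} and \code{lcrBeds} (named
#'   file paths).
#' @export
readCohort <- function(dir) {
  sheet <- read.table(file.path(dir, "sample_sheet.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
  repFiles <- sort(list.files(dir, "^array_rep[0-9]+\\.vcf$",
                              full.names = TRUE))
  array <- lapply(seq_along(repFiles), function(k)
    readGenotypeVcf(repFiles[k], sampleSheet = sheet,
                    replicateId = sprintf("rep%d", k)))
  names(array) <- sprintf("rep%d", seq_along(repFiles))
  ann <- read.table(file.path(dir, "annotations.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  trPath <- file.path(dir, "transcripts.tsv")
  beds <- file.path(dir, sprintf("lcr_%s.bed",
                                 c("SimpleRepeat", "Microsatellite",
                                   "RepeatMasker")))
  names(beds) <- c("SimpleRepeat", "Microsatellite", "RepeatMasker")
  list(truth = readGenotypeVcf(file.path(dir, "truth.vcf"),
                               replicateId = "truth"),
       array = array,
       wgs = readGenotypeVcf(file.path(dir, "wgs.vcf"),
                             replicateId = "wgs"),
       annotations = ann,
       transcripts = if (file.exists(trPath))
         read.table(trPath, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE) else NULL,
       sampleSheet = sheet,
       lcrBeds = beds[file.exists(beds)])
}
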