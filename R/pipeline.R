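## End-to-end orchestration: simulate (or load) -> QC -> compare ->
## stratify -> report.

.sumTallies <- function(tables) {
  base <- tables[[1]]
  for (k in seq_along(tables)[-1]) {
    stopifnot(identical(tables[[k]]$assay_id, base$assay_id))
    for (col in c("a", "b", "c", "d", "z", "n_na"))
      base[[col]] <- base[[col]] + tables[[k]][[col]]
  }
  div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  base$concordance <- div(base$a + base$c,
                          base$a + base$b + base$c + base$d + base$z)
  base$sensitivity <- div(base$a, base$a + base$d)
  base$specificity <- div(base$c, base$c + base$b)
  base$ppv <- div(base$a, base$a + base$b)
  base
}

#' Run the full validation pipeline
#'
#' Executes simulate (or load) -> per-replicate QC -> replicate
#' reproducibility -> harmonization -> array-vs-truth and WGS-vs-truth
#' comparison -> per-assay stratification -> panel selection, and
#' returns every table. Sample-replicates flagged \code{CONTAMINATED} or
#' \code{Z_OUTLIER} are excluded from the headline metric tables and
#' reported separately. WGS calls are masked below the depth/quality
#' floor before use as a comparison set, and assays genotyped in fewer
#' than \code{wgsMinCoverage} of WGS samples are excluded from analyses
#' involving WGS. Deterministic for a fixed config seed in simulate
#' mode.
#'
#' @param config a \linkS4class{SimConfig} (simulate mode); ignored when
#'   \code{inputDir} is given.
#' @param inputDir directory of cohort files from
#'   \code{\link{writeCohort}} (user-files mode).
#' @param callRateMin,contaminationMax,zCutoff QC flag thresholds.
#' @param wgsMinDepth,wgsMinQual confidence floor on WGS calls.
#' @param wgsMinCoverage minimum fraction of WGS samples genotyped for
#'   an assay to enter WGS comparisons.
#' @param pcaSubsample loci subsampled for the PCA structure check.
#' @return a \code{ValidationReport}: list with \code{qc},
#'   \code{replicate_summary}, \code{chip_positions}, \code{pca},
#'   \code{global_metrics}, \code{per_assay} (pooled across kept
#'   replicates), \code{per_assay_wgs}, \code{three_way},
#'   \code{strata} (named list of tables), \code{panel},
#'   \code{annotations}, \code{excluded_replicates} and \code{summary}.
#' @export
runValidation <- function(config = simConfig(), inputDir = NULL,
                          callRateMin = 0.98, contaminationMax = 0.025,
                          zCutoff = -4, wgsMinDepth = 20, wgsMinQual = 30,
                          wgsMinCoverage = 0.9, pcaSubsample = 10000) {
  log <- list()
  note <- function(stage, msg)
    log[[length(log) + 1]] <<- data.frame(stage = stage, message = msg)

  if (is.null(inputDir)) {
    validObject(config)
    cohort <- simulateCohort(config)
    note("input", sprintf("simulated cohort: %d samples x %d assays, seed %d",
                          config@nSamples, config@nAssays,
                          as.integer(config@seed)))
  } else {
    cohort <- readCohort(inputDir)
    note("input", sprintf("loaded cohort from %s", inputDir))
  }
  truth <- cohort$truth
  reps <- cohort$array
  wgs <- cohort$wgs

  qc <- sampleQC(reps, callRateMin = callRateMin,
                 contaminationMax = contaminationMax, zCutoff = zCutoff)
  conc <- pairwiseReplicateConcordance(reps)
  repSum <- if (length(reps) == 3) replicateSummary(qc, conc) else NULL
  chipPos <- chipPositionSummary(qc)
  pca <- pcaStructure(reps[[1]], nSubsample = pcaSubsample,
                      seed = if (is.null(inputDir)) config@seed else 1)
  flagged <- qc[grepl("CONTAMINATED|Z_OUTLIER", qc$flags), ]
  note("qc", sprintf("%d of %d sample-replicates flagged for exclusion",
                     nrow(flagged), nrow(qc)))

  harm <- harmonize(c(list(truth = truth), reps, list(wgs = wgs)))
  note("harmonize", sprintf("%d common loci, %d excluded",
                            harm$n_common, nrow(harm$excluded)))
  hTruth <- harm$matrices$truth
  hReps <- harm$matrices[sprintf("rep%d", seq_along(reps))]
  hWgs <- maskLowConfidence(harm$matrices$wgs, minDepth = wgsMinDepth,
                            minQual = wgsMinQual)
  covOk <- assayCoverageOk(hWgs, minFraction = wgsMinCoverage)
  note("wgs_filter",
       sprintf("%d of %d assays pass the %.0f%% WGS coverage floor",
               sum(covOk), length(covOk), 100 * wgsMinCoverage))

  keptSamples <- lapply(seq_along(hReps), function(r)
    setdiff(colnames(hReps[[r]]),
            flagged$sample_id[flagged$replicate == r]))

  global <- list()
  perAssayList <- list()
  for (r in seq_along(hReps)) {
    tal <- tallyPairs(hReps[[r]], hTruth, samples = keptSamples[[r]])
    global[[sprintf("rep%d_vs_truth", r)]] <-
      c(tallyCounts(tal), computeMetrics(tal))
    perAssayList[[r]] <- perAssayMetrics(hReps[[r]], hTruth,
                                         samples = keptSamples[[r]])
  }
  wgsTal <- tallyPairs(hWgs[covOk, ], hTruth[covOk, ])
  global$wgs_vs_truth <- c(tallyCounts(wgsTal), computeMetrics(wgsTal))
  globalDf <- data.frame(comparison = names(global),
                         do.call(rbind, global), row.names = NULL)

  perAssay <- .sumTallies(perAssayList)
  perAssayWgs <- perAssayMetrics(hWgs, hTruth)
  eligRows <- mcols(rowRanges(hTruth))$cluster_qc_pass %in% TRUE &
    .isAutosome(hTruth)
  keepIds <- perAssay$assay_id[covOk[eligRows]]
  three <- threeWayPpv(perAssay[perAssay$assay_id %in% keepIds, ],
                       perAssayWgs[perAssayWgs$assay_id %in% keepIds, ])
  note("compare", sprintf("three-way PPV over %d assays", three$n))

  ann <- annotateAssays(truth,
                        lcrBeds = if (!is.null(inputDir))
                          cohort$lcrBeds else NULL)
  if (!is.null(inputDir) && !is.null(cohort$annotations)) {
    ## panel flags travel in the annotation table, not the VCF
    m <- match(ann$assay_id, cohort$annotations$assay_id)
    for (col in c("in_transcript_window", "clinvar_path", "hgmd",
                  "curated_mvl"))
      if (!is.null(cohort$annotations[[col]]))
        ann[[col]] <- cohort$annotations[[col]][m] %in% TRUE
  }
  strata <- list(
    variant_type = stratifiedMetrics(perAssay, ann, "variant_type"),
    change_class = stratifiedMetrics(perAssay, ann, "change_class"),
    af_bin = stratifiedMetrics(perAssay, ann, "af_bin"),
    lcr = stratifiedMetrics(perAssay, ann, "any_lcr"))
  transcripts <- if (is.null(inputDir)) metadata(truth)$transcripts
                 else cohort$transcripts
  panel <- if (!is.null(transcripts) && nrow(transcripts))
    selectMapPanel(ann, transcripts) else NULL
  note("stratify", sprintf("%d annotated assays", nrow(ann)))

  summary <- list(
    n_samples = ncol(truth), n_assays = nrow(truth),
    n_replicates = length(reps),
    n_eligible_assays =
      sum(mcols(rowRanges(truth))$cluster_qc_pass %in% TRUE),
    n_common_loci = harm$n_common,
    n_flagged_replicates = nrow(flagged),
    n_assays_wgs_covered = sum(covOk),
    mean_call_rate = mean(qc$call_rate),
    frac_call_rate_gt_098 = mean(qc$call_rate > 0.98),
    frac_concordance_gt_0999 = mean(
      rowSums(as.matrix(conc[, c("r1r2", "r2r3", "r1r3")]) > 0.999) == 3),
    global = global,
    frac_ppv_1 = mean(perAssay$ppv[!is.na(perAssay$ppv)] == 1))
  out <- list(qc = qc, replicate_summary = repSum,
              chip_positions = chipPos, pca = pca,
              replicate_concordance = conc,
              global_metrics = globalDf, per_assay = perAssay,
              per_assay_wgs = perAssayWgs, three_way = three,
              strata = strata, panel = panel, annotations = ann,
              excluded_replicates = flagged,
              summary = summary, log = do.call(rbind, log))
  class(out) <- c("ValidationReport", "list")
  out
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat(sprintf("ValidationReport: %d samples, %d assays, %d replicates\n",
              x$summary$n_samples, x$summary$n_assays,
              x$summary$n_replicates))
  cat(sprintf("  flagged replicates excluded from headline metrics: %d\n",
              x$summary$n_flagged_replicates))
  print(x$global_metrics[, c("comparison", "concordance", "sensitivity",
                             "specificity", "ppv")], digits = 4)
  invisible(x)
}

#' Write a validation report to disk
#'
#' One TSV per table (stable column order), a machine-readable JSON
#' summary and a structured log. Re-running on identical inputs yields
#' byte-identical files.
#'
#' @param report a \code{ValidationReport} from
#'   \code{\link{runValidation}}.
#' @param outDir output directory, created if needed.
#' @return named vector of written paths, invisibly.
#' @export
writeReport <- function(report, outDir) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  paths <- character()
  put <- function(df, name) {
    p <- file.path(outDir, paste0(name, ".tsv"))
    .writeTsv(df, p)
    paths[name] <<- p
  }
  put(report$qc, "qc")
  if (!is.null(report$replicate_summary))
    put(report$replicate_summary, "replicate_summary")
  put(report$chip_positions, "chip_position_summary")
  put(data.frame(sample_id = rownames(report$pca), report$pca,
                 row.names = NULL), "pca_coordinates")
  put(report$global_metrics, "global_metrics")
  put(report$per_assay, "per_assay_metrics")
  put(report$per_assay_wgs, "per_assay_metrics_wgs")
  for (nm in names(report$strata))
    put(report$strata[[nm]], paste0("strata_", nm))
  if (!is.null(report$panel)) put(report$panel$report, "panel_report")
  put(data.frame(cell = names(report$three_way$counts),
                 count = as.vector(report$three_way$counts),
                 fraction = as.vector(report$three_way$fractions)),
      "three_way_ppv")
  put(report$excluded_replicates, "excluded_replicates")
  put(report$log, "log")
  p <- file.path(outDir, "summary.json")
  jsonlite::write_json(report$summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths["summary"] <- p
  invisible(paths)
}
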