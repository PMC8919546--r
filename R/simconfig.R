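## Default allele-frequency spectrum: 13 alternate-allele-frequency bins with
## assay proportions matching a genome-wide screening-array manifest
## (rare-variant heavy; bins on the fraction scale, first bin closed).
.DEFAULT_AF_SPECTRUM <- data.frame(
  lower = c(0, 0.001, 0.01, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50, 0.60,
            0.70, 0.80, 0.90),
  upper = c(0.001, 0.01, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50, 0.60, 0.70,
            0.80, 0.90, 1),
  prop  = c(17830, 148959, 113374, 63688, 84729, 56601, 39684, 30095,
            25078, 21944, 20866, 15612, 4552) / 643012
)

.DEFAULT_VARIANT_TYPE_FRACTIONS <- c(SNV = 656601, INS = 1110, DEL = 2799,
                                     MAV = 616) / 661126

#' Configuration of the synthetic genotyping cohort
#'
#' \code{SimConfig} parameterizes the whole synthetic study: cohort and
#' panel size, the alternate-allele-frequency spectrum the assays target,
#' the strata composition (variant type, transition/transversion,
#' complementary transversions, low-complexity-region membership, panel
#' flags), the per-stratum genotyping error model of the array, the
#' WGS-like call model, the contamination schedule, the chip layout with
#' its row-wise quality gradient, and the master seed. Defaults emulate a
#' triplicate screening-array study of 263 samples: a rare-variant-heavy
#' 13-bin AF spectrum, 99.3\% SNV assays of which 79.6\% are transitions,
#' an 8\% cluster-QC failure rate, a 0.0017 no-call rate, and a GenCall
#' score gradient giving a 10th-percentile score near 0.60 in chip row 1
#' falling to 0.55 in row 12.
#'
#' @aliases SimConfig-class
#' @export
setClass("SimConfig",
  representation(
    nSamples = "numeric", nAssays = "numeric", nReplicates = "numeric",
    afSpectrum = "data.frame",
    variantTypeFractions = "numeric",
    transitionFraction = "numeric",
    complementaryTvFraction = "numeric",
    lcrFractions = "numeric",
    clusterQcFailRate = "numeric",
    errorModel = "list",
    errorMultipliers = "numeric",
    wgsModel = "list",
    contamination = "numeric",
    chipLayout = "list",
    bafModel = "list",
    panelModel = "list",
    seed = "numeric"))

.checkProb <- function(x, nm) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    sprintf("'%s' must lie in [0, 1]", nm)
  else character()
}

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nSamples < 1) msg <- c(msg, "'nSamples' must be >= 1")
  if (object@nAssays < 1)  msg <- c(msg, "'nAssays' must be >= 1")
  if (object@nReplicates < 1) msg <- c(msg, "'nReplicates' must be >= 1")
  sp <- object@afSpectrum
  if (!all(c("lower", "upper", "prop") %in% names(sp)))
    msg <- c(msg, "'afSpectrum' needs columns lower, upper, prop")
  else {
    msg <- c(msg, .checkProb(sp$lower, "afSpectrum$lower"),
             .checkProb(sp$upper, "afSpectrum$upper"))
    if (abs(sum(sp$prop) - 1) > 1e-6)
      msg <- c(msg, "'afSpectrum' proportions must sum to 1")
  }
  if (abs(sum(object@variantTypeFractions) - 1) > 1e-6)
    msg <- c(msg, "'variantTypeFractions' must sum to 1")
  msg <- c(msg,
           .checkProb(object@transitionFraction, "transitionFraction"),
           .checkProb(object@complementaryTvFraction,
                      "complementaryTvFraction"),
           .checkProb(object@lcrFractions, "lcrFractions"),
           .checkProb(object@clusterQcFailRate, "clusterQcFailRate"),
           .checkProb(unlist(object@errorModel), "errorModel"))
  if (length(object@contamination) &&
      (any(object@contamination < 0) || any(object@contamination >= 1)))
    msg <- c(msg, "'contamination' fractions must lie in [0, 1)")
  if (!is.null(object@wgsModel$meanDepth) && object@wgsModel$meanDepth < 0)
    msg <- c(msg, "'wgsModel$meanDepth' must be non-negative")
  if (object@seed < 0 || object@seed > 2^31 - 10)
    msg <- c(msg, "'seed' must be a non-negative 32-bit integer")
  if (length(msg)) msg else TRUE
})

#' @param nSamples,nAssays,nReplicates cohort size, assay-panel size,
#'   number of array replicates per sample.
#' @param afSpectrum data.frame with columns \code{lower}, \code{upper},
#'   \code{prop}: allele-frequency bins (fractions) and the proportion of
#'   assays targeting each bin.
#' @param variantTypeFractions named proportions of SNV/INS/DEL/MAV assays.
#' @param transitionFraction fraction of SNV assays that are transitions.
#' @param complementaryTvFraction fraction of transversion assays between
#'   complementary bases (A<->T, C<->G).
#' @param lcrFractions named per-class probabilities that an assay falls in
#'   a low-complexity class (\code{SimpleRepeat}, \code{Microsatellite},
#'   \code{RepeatMasker}); classes are independent and may overlap.
#' @param clusterQcFailRate probability an assay fails cluster-file QC.
#' @param errorModel list of per-call array error probabilities:
#'   \code{hetToHom}, \code{homToHet}, \code{fpHomRef} (false-positive alt
#'   call at hom-ref truth), \code{fnAlt} (call of hom-ref at alt-carrying
#'   truth), \code{noCall}. Events are mutually exclusive per call, applied
#'   no-call first.
#' @param errorMultipliers named multipliers applied to the miscall
#'   probabilities for loci in the harder strata (transversion,
#'   complementary_tv, INS, DEL, MAV, lcr); multipliers for co-occurring
#'   strata compound.
#' @param wgsModel list: \code{meanDepth}, \code{depthDispersion}
#'   (negative-binomial size), \code{qualMean}, \code{qualSd},
#'   \code{errorRate}, \code{noCall}, \code{assayDropout},
#'   \code{dropoutMissingRate}.
#' @param contamination named numeric of mixing fractions alpha in [0,1);
#'   names are \code{"<sample_id>:<replicate>"}.
#' @param chipLayout list: \code{rows}, \code{cols} (wells per chip =
#'   rows*cols), \code{gcMeanRow1}, \code{gcMeanRowMax},
#'   \code{gcConcentration} (Beta model of GenCall scores with a linear
#'   row-wise decline in the mean), \code{edgeNoCallRate} (extra no-call
#'   probability in the two bottom rows of column 1).
#' @param bafModel list of B-allele-frequency noise parameters:
#'   \code{homSd} (additive SD at the homozygous poles), \code{hetSd}
#'   (SD of the heterozygous cluster around 0.5) and \code{relSd}
#'   (multiplicative SD on the displacement of a homozygous call from
#'   its pole, the dominant noise on contamination-displaced BAF).
#' @param panelModel list: \code{nGenes}, \code{geneWidth}, \code{flank}
#'   and conditional annotation probabilities \code{pClinvar},
#'   \code{pHgmd}, \code{pCurated} for the actionable-panel chain.
#' @param seed master seed; the truth, array and WGS stages use
#'   \code{seed}, \code{seed + 1} and \code{seed + 2}.
#' @return a validated \code{SimConfig}.
#' @rdname SimConfig-class
#' @export
simConfig <- function(nSamples = 263, nAssays = 10000, nReplicates = 3,
                      afSpectrum = .DEFAULT_AF_SPECTRUM,
                      variantTypeFractions = .DEFAULT_VARIANT_TYPE_FRACTIONS,
                      transitionFraction = 0.796,
                      complementaryTvFraction = 10635 / 133663,
                      lcrFractions = c(SimpleRepeat = 0.0007,
                                       Microsatellite = 0.0005,
                                       RepeatMasker = 0.339),
                      clusterQcFailRate = 0.08,
                      errorModel = list(hetToHom = 2e-4, homToHet = 1e-4,
                                        fpHomRef = 5e-5, fnAlt = 1e-4,
                                        noCall = 0.0017),
                      errorMultipliers = c(transversion = 2,
                                           complementary_tv = 4,
                                           INS = 10, DEL = 20, MAV = 5,
                                           lcr = 3),
                      wgsModel = list(meanDepth = 37, depthDispersion = 40,
                                      qualMean = 60, qualSd = 15,
                                      errorRate = 5e-5, noCall = 0.002,
                                      assayDropout = 0.005,
                                      dropoutMissingRate = 0.5),
                      contamination = numeric(0),
                      chipLayout = list(rows = 12, cols = 2,
                                        gcMeanRow1 = 0.763,
                                        gcMeanRowMax = 0.720,
                                        gcConcentration = 12,
                                        edgeNoCallRate = 0.01),
                      bafModel = list(homSd = 0.002, hetSd = 0.03,
                                      relSd = 0.15),
                      panelModel = list(nGenes = 59, geneWidth = 20000,
                                        flank = 1000,
                                        pClinvar = 5075 / 6841,
                                        pHgmd = 3082 / 5075,
                                        pCurated = 1883 / 3082),
                      seed = 1) {
  defEM <- list(hetToHom = 2e-4, homToHet = 1e-4, fpHomRef = 5e-5,
                fnAlt = 1e-4, noCall = 0.0017)
  errorModel <- utils::modifyList(defEM, errorModel)
  bad <- setdiff(names(errorModel), names(defEM))
  if (length(bad))
    stop("unknown errorModel field(s): ", paste(bad, collapse = ", "))
  defW <- list(meanDepth = 37, depthDispersion = 40, qualMean = 60,
               qualSd = 15, errorRate = 5e-5, noCall = 0.002,
               assayDropout = 0.005, dropoutMissingRate = 0.5)
  wgsModel <- utils::modifyList(defW, wgsModel)
  defL <- list(rows = 12, cols = 2, gcMeanRow1 = 0.763,
               gcMeanRowMax = 0.720, gcConcentration = 12,
               edgeNoCallRate = 0.01)
  chipLayout <- utils::modifyList(defL, chipLayout)
  defB <- list(homSd = 0.002, hetSd = 0.03, relSd = 0.15)
  bafModel <- utils::modifyList(defB, bafModel)
  defP <- list(nGenes = 59, geneWidth = 20000, flank = 1000,
               pClinvar = 5075 / 6841, pHgmd = 3082 / 5075,
               pCurated = 1883 / 3082)
  panelModel <- utils::modifyList(defP, panelModel)
  new("SimConfig",
      nSamples = nSamples, nAssays = nAssays, nReplicates = nReplicates,
      afSpectrum = afSpectrum,
      variantTypeFractions = variantTypeFractions,
      transitionFraction = transitionFraction,
      complementaryTvFraction = complementaryTvFraction,
      lcrFractions = lcrFractions,
      clusterQcFailRate = clusterQcFailRate,
      errorModel = errorModel, errorMultipliers = errorMultipliers,
      wgsModel = wgsModel, contamination = contamination,
      chipLayout = chipLayout, bafModel = bafModel,
      panelModel = panelModel, seed = seed)
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d samples x %d assays, %d replicates (seed %d)\n",
              object@nSamples, object@nAssays, object@nReplicates,
              as.integer(object@seed)))
  cat(sprintf("  no-call rate %.4g, cluster-QC fail rate %.3g, %d AF bins\n",
              object@errorModel$noCall, object@clusterQcFailRate,
              nrow(object@afSpectrum)))
  if (length(object@contamination))
    cat(sprintf("  contaminated replicates: %s\n",
                paste(sprintf("%s (alpha=%.3g)", names(object@contamination),
                              object@contamination), collapse = ", ")))
  invisible(NULL)
})
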