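#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges granges findOverlaps countOverlaps
#'   reduce seqnames strand start end width mcols mcols<- strand<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame queryHits subjectHits metadata metadata<-
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqnames<-
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Configuration for the synthetic ChIP-BS-Seq generator
#'
#' `SimConfig` bundles every tunable of the synthetic-data module: genome
#' and repeat-family geometry, per-family CpG density and methylation
#' probability, pol III occupancy enrichment, bisulphite chemistry
#' (conversion and conversion-failure rates), sequencing error, the
#' unmethylated spike-in contig, and library depths. The defaults emulate
#' the statistical structure of a HeLa pol III ChIP-BS-Seq experiment at
#' toy scale: three Alu-like SINE families whose CpG density and
#' methylation probability fall from a young, heavily methylated family to
#' an old, lowly methylated one, a handful of CpG-poor tRNA-gene-like
#' loci, and a fully unmethylated spike-in contributing ~2% of reads as a
#' conversion control.
#'
#' @slot genomeLength integer, main contig length in bases.
#' @slot nFamilies integer, number of SINE-like repeat families.
#' @slot copiesPerFamily integer, genomic copies per family.
#' @slot elementLength integer, family consensus length in bases.
#' @slot familyDivergence numeric, per-base substitution probability
#'   applied independently to each copy.
#' @slot cpgDensity numeric vector (one per family), CpGs per 100 bp of
#'   consensus.
#' @slot methProb numeric vector (one per family), probability in [0,1]
#'   that a CpG inside a family element is methylated on a given molecule.
#' @slot familyClass character vector (one per family), annotation class.
#' @slot nTrnaLoci integer, number of short CpG-poor tRNA-gene-like loci.
#' @slot trnaMethProb numeric, CpG methylation probability at tRNA-like loci.
#' @slot backgroundMethProb numeric, methylation probability of CpGs
#'   outside annotated elements.
#' @slot nOccupiedLoci integer, elements carrying pol III occupancy.
#' @slot occupancyFold numeric, fragment-sampling enrichment multiplier
#'   over occupied loci in the ChIP library.
#' @slot fragmentLenMean,fragmentLenSd numeric, fragment length
#'   distribution (truncated normal, minimum = read length).
#' @slot readLength integer, bases sequenced per fragment end.
#' @slot conversionRate numeric, probability an unmethylated C reads as T.
#' @slot conversionFailureRate numeric, probability a methylated C reads
#'   as T.
#' @slot sequencingErrorRate numeric, per-base substitution probability
#'   applied after conversion.
#' @slot spikeInFraction numeric, proportion of reads drawn from the
#'   unmethylated spike-in contig (default 0.02).
#' @slot spikeInLength integer, spike-in contig length.
#' @slot chipDepth,inputDepth integer, reads per library.
#' @slot seed integer, RNG seed; identical configuration and seed give
#'   byte-identical outputs.
#' @seealso [simConfig()], [buildToyGenome()], [simulateReads()]
#' @export
setClass("SimConfig",
  representation(
    genomeLength = "integer", nFamilies = "integer",
    copiesPerFamily = "integer", elementLength = "integer",
    familyDivergence = "numeric", cpgDensity = "numeric",
    methProb = "numeric", familyClass = "character",
    nTrnaLoci = "integer", trnaMethProb = "numeric",
    backgroundMethProb = "numeric",
    nOccupiedLoci = "integer", occupancyFold = "numeric",
    fragmentLenMean = "numeric", fragmentLenSd = "numeric",
    readLength = "integer",
    conversionRate = "numeric", conversionFailureRate = "numeric",
    sequencingErrorRate = "numeric",
    spikeInFraction = "numeric", spikeInLength = "integer",
    chipDepth = "integer", inputDepth = "integer", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  probs <- c(object@familyDivergence, object@cpgDensity / 100,
             object@methProb, object@trnaMethProb,
             object@backgroundMethProb, object@conversionRate,
             object@conversionFailureRate, object@sequencingErrorRate,
             object@spikeInFraction)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "all probabilities must lie in [0, 1]")
  lens <- c(object@genomeLength, object@nFamilies, object@copiesPerFamily,
            object@elementLength, object@readLength, object@spikeInLength)
  if (any(lens <= 0L))
    msg <- c(msg, "lengths and counts must be positive")
  if (any(c(object@chipDepth, object@inputDepth, object@nOccupiedLoci,
            object@nTrnaLoci) < 0L))
    msg <- c(msg, "depths, occupied loci and tRNA loci must be >= 0")
  if (length(object@cpgDensity) != object@nFamilies ||
      length(object@methProb) != object@nFamilies ||
      length(object@familyClass) != object@nFamilies)
    msg <- c(msg, "cpgDensity, methProb and familyClass must have one value per family")
  if (object@occupancyFold < 1)
    msg <- c(msg, "occupancyFold must be >= 1")
  if (object@fragmentLenMean < object@readLength)
    msg <- c(msg, "fragmentLenMean must be >= readLength")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic-data configuration
#'
#' Constructor for [SimConfig-class] with study-scale defaults. Family
#' vectors (`cpgDensity`, `methProb`, `familyClass`) are recycled to
#' `nFamilies`.
#'
#' Default per-family methylation probabilities (0.60, 0.35, 0.13) mirror
#' the contrast between young heavily methylated, intermediate, and old
#' lowly methylated Alu subfamilies; the default conversion rate 0.9976 is
#' the level a well-converted library achieves, and 2% of reads come from
#' the fully unmethylated spike-in contig.
#'
#' @param genomeLength,nFamilies,copiesPerFamily,elementLength,familyDivergence
#'   Genome geometry; see [SimConfig-class].
#' @param cpgDensity,methProb,familyClass Per-family CpG density (per 100
#'   bp), methylation probability and annotation class.
#' @param nTrnaLoci,trnaMethProb,backgroundMethProb Methylation of
#'   tRNA-like loci and of background CpGs.
#' @param nOccupiedLoci,occupancyFold Occupancy truth: how many annotated
#'   elements carry pol III and the ChIP fragment-sampling fold over them.
#' @param fragmentLenMean,fragmentLenSd,readLength Fragmentation and read
#'   length.
#' @param conversionRate,conversionFailureRate,sequencingErrorRate
#'   Bisulphite chemistry and sequencing noise.
#' @param spikeInFraction,spikeInLength Unmethylated spike-in control.
#' @param chipDepth,inputDepth Reads per library.
#' @param seed Integer RNG seed.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(genomeLength = 50000L, chipDepth = 2000L,
#'                  inputDepth = 2000L, seed = 7L)
#' cfg
#' @export
simConfig <- function(genomeLength = 200000L, nFamilies = 3L,
                      copiesPerFamily = 30L, elementLength = 300L,
                      familyDivergence = 0.02,
                      cpgDensity = c(8, 5, 2.5),
                      methProb = c(0.60, 0.35, 0.13),
                      familyClass = "SINE",
                      nTrnaLoci = 10L, trnaMethProb = 0.05,
                      backgroundMethProb = 0.75,
                      nOccupiedLoci = 20L, occupancyFold = 6,
                      fragmentLenMean = 170, fragmentLenSd = 35,
                      readLength = 101L,
                      conversionRate = 0.9976,
                      conversionFailureRate = 0.003,
                      sequencingErrorRate = 0.001,
                      spikeInFraction = 0.02, spikeInLength = 20000L,
                      chipDepth = 50000L, inputDepth = 50000L,
                      seed = 1L) {
  nFamilies <- as.integer(nFamilies)
  new("SimConfig",
      genomeLength = as.integer(genomeLength), nFamilies = nFamilies,
      copiesPerFamily = as.integer(copiesPerFamily),
      elementLength = as.integer(elementLength),
      familyDivergence = familyDivergence,
      cpgDensity = rep_len(cpgDensity, nFamilies),
      methProb = rep_len(methProb, nFamilies),
      familyClass = rep_len(familyClass, nFamilies),
      nTrnaLoci = as.integer(nTrnaLoci), trnaMethProb = trnaMethProb,
      backgroundMethProb = backgroundMethProb,
      nOccupiedLoci = as.integer(nOccupiedLoci),
      occupancyFold = occupancyFold,
      fragmentLenMean = fragmentLenMean, fragmentLenSd = fragmentLenSd,
      readLength = as.integer(readLength),
      conversionRate = conversionRate,
      conversionFailureRate = conversionFailureRate,
      sequencingErrorRate = sequencingErrorRate,
      spikeInFraction = spikeInFraction,
      spikeInLength = as.integer(spikeInLength),
      chipDepth = as.integer(chipDepth), inputDepth = as.integer(inputDepth),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: ", object@genomeLength, " bp genome, ",
      object@nFamilies, " families x ", object@copiesPerFamily,
      " copies (", object@elementLength, " bp), ",
      object@nTrnaLoci, " tRNA-like loci\n", sep = "")
  cat("  methProb: ", paste(format(object@methProb), collapse = ", "),
      "; CpG/100bp: ", paste(format(object@cpgDensity), collapse = ", "),
      "\n", sep = "")
  cat("  occupancy: ", object@nOccupiedLoci, " loci at ",
      object@occupancyFold, "-fold; depths chip=", object@chipDepth,
      " input=", object@inputDepth, "\n", sep = "")
  cat("  conversion=", object@conversionRate, " failure=",
      object@conversionFailureRate, " spikeIn=", object@spikeInFraction,
      " seed=", object@seed, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## PointData
## ---------------------------------------------------------------------------

#' Single-position point data for one sequencing library
#'
#' Reads are collapsed to single genomic positions (shifted toward the
#' fragment midpoint by half the peak shift) with their multi-mapper
#' weights; the window scanner and element scorer consume this
#' representation.
#'
#' @slot positions named list (per contig) of numeric 0-based positions.
#' @slot weights named list (per contig) of numeric weights parallel to
#'   `positions`.
#' @slot librarySize numeric, total weight over all contigs.
#' @slot peakShift numeric, the shift (bp) applied when the object was
#'   built.
#' @slot contigLengths named numeric, contig lengths used for clipping.
#' @seealso [toPointData()], [scanWindows()], [scoreElements()]
#' @export
setClass("PointData",
  representation(positions = "list", weights = "list",
                 librarySize = "numeric", peakShift = "numeric",
                 contigLengths = "numeric"))

setValidity("PointData", function(object) {
  msg <- character(0)
  if (!identical(names(object@positions), names(object@weights)))
    msg <- c(msg, "positions and weights must cover the same contigs")
  for (ctg in names(object@positions)) {
    if (length(object@positions[[ctg]]) != length(object@weights[[ctg]]))
      msg <- c(msg, sprintf("contig %s: positions/weights length mismatch", ctg))
    len <- object@contigLengths[ctg]
    if (!is.na(len) && length(object@positions[[ctg]]) &&
        (min(object@positions[[ctg]]) < 0 ||
         max(object@positions[[ctg]]) >= len))
      msg <- c(msg, sprintf("contig %s: positions outside contig bounds", ctg))
  }
  tot <- sum(vapply(object@weights, sum, numeric(1)))
  if (abs(tot - object@librarySize) > 1e-6 * max(1, tot))
    msg <- c(msg, "librarySize must equal the total weight")
  if (length(msg)) msg else TRUE
})

#' @describeIn PointData-class Total weight of the library.
#' @param object A `PointData` object.
#' @export
librarySize <- function(object) object@librarySize

setMethod("show", "PointData", function(object) {
  cat("PointData: ", format(object@librarySize, digits = 8),
      " total weight on ", length(object@positions),
      " contig(s), peak shift ", object@peakShift, " bp\n", sep = "")
})

## ---------------------------------------------------------------------------
## CytosineCalls
## ---------------------------------------------------------------------------

#' Per-cytosine methylation calls
#'
#' A [GenomicRanges::GRanges] subclass with one width-1 range per observed
#' cytosine (on its own strand; minus-strand cytosines are reported at the
#' plus-strand coordinate of their base with strand `-`). Metadata columns
#' `context` (CpG/CHG/CHH), `meth` and `unmeth` hold weighted observation
#' counts: each read placement contributes its multi-mapper weight 1/k.
#'
#' @seealso [callCytosines()], [methFraction()], [estimateConversion()]
#' @export
setClass("CytosineCalls", contains = "GRanges")

setValidity("CytosineCalls", function(object) {
  msg <- character(0)
  need <- c("context", "meth", "unmeth")
  if (!all(need %in% colnames(mcols(object))))
    msg <- c(msg, "mcols must contain context, meth and unmeth")
  else {
    if (any(mcols(object)$meth < 0) || any(mcols(object)$unmeth < 0))
      msg <- c(msg, "meth and unmeth counts must be >= 0")
    if (!all(mcols(object)$context %in% c("CpG", "CHG", "CHH")))
      msg <- c(msg, "context must be CpG, CHG or CHH")
  }
  if (length(object) && any(width(object) != 1L))
    msg <- c(msg, "all ranges must have width 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn CytosineCalls-class Weighted methylated counts.
#' @param object A `CytosineCalls` object.
#' @export
methCount <- function(object) mcols(object)$meth

#' @describeIn CytosineCalls-class Weighted unmethylated counts.
#' @export
unmethCount <- function(object) mcols(object)$unmeth

#' @describeIn CytosineCalls-class Weighted coverage (meth + unmeth).
#' @export
callCoverage <- function(object) mcols(object)$meth + mcols(object)$unmeth

#' @describeIn CytosineCalls-class Fraction methylated; `NA` where
#'   coverage is zero.
#' @export
methFraction <- function(object) {
  cov <- callCoverage(object)
  ifelse(cov > 0, methCount(object) / cov, NA_real_)
}

setMethod("show", "CytosineCalls", function(object) {
  cat("CytosineCalls with ", length(object), " cytosines (",
      sum(mcols(object)$context == "CpG"), " CpG); total weighted coverage ",
      format(sum(callCoverage(object)), digits = 8), "\n", sep = "")
  if (length(object)) callNextMethod()
})

## ---------------------------------------------------------------------------
## ConsensusIndex
## ---------------------------------------------------------------------------

#' Repeat-family consensus index for bisulphite realignment
#'
#' Family consensus sequences concatenated with an N spacer, held together
#' with the two collapsed (three-letter) forms used for bisulphite
#' matching: C-to-T for original-top-strand reads and G-to-A for
#' original-bottom-strand reads.
#'
#' @slot consensi [Biostrings::DNAStringSet] of family consensus
#'   sequences, named by family.
#' @slot spacer integer, number of N bases separating concatenated
#'   consensi (an internal detail of the index; output coordinates are
#'   always per-family).
#' @slot catOT,catOB character, concatenated collapsed index (C>T, G>A).
#' @slot offsets named integer, 0-based start of each family in the
#'   concatenated index.
#' @seealso [consensusIndex()], [bisulfiteRealign()]
#' @export
setClass("ConsensusIndex",
  representation(consensi = "DNAStringSet", spacer = "integer",
                 catOT = "character", catOB = "character",
                 offsets = "integer"))

setValidity("ConsensusIndex", function(object) {
  msg <- character(0)
  nm <- names(object@consensi)
  if (is.null(nm) || anyDuplicated(nm))
    msg <- c(msg, "consensus sequences must have unique family names")
  if (any(Biostrings::alphabetFrequency(object@consensi)[, "N"] > 0))
    msg <- c(msg, "consensus sequences must not contain N")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ConsensusIndex", function(object) {
  cat("ConsensusIndex: ", length(object@consensi), " families (",
      paste(names(object@consensi), collapse = ", "), "), spacer ",
      object@spacer, " N\n", sep = "")
})

## ---------------------------------------------------------------------------
## ConsensusProfile
## ---------------------------------------------------------------------------

#' Per-base methylation profile on family consensus coordinates
#'
#' Weighted methylated/unmethylated counts at every consensus position of
#' one repeat family, from reads realigned to the family consensus in
#' collapsed bisulphite space. The fraction methylated is defined only
#' where coverage is positive.
#'
#' @slot family character, family name.
#' @slot consensus character, the consensus sequence (array length =
#'   nchar(consensus)).
#' @slot meth,unmeth numeric arrays of weighted counts per 0-based
#'   consensus position.
#' @slot blocks list of optional promoter annotations (e.g. A-block,
#'   B-block intervals), each a c(start, end) 0-based half-open pair.
#' @seealso [profileFromAlignments()], [profileFraction()]
#' @export
setClass("ConsensusProfile",
  representation(family = "character", consensus = "character",
                 meth = "numeric", unmeth = "numeric", blocks = "list"))

setValidity("ConsensusProfile", function(object) {
  msg <- character(0)
  len <- nchar(object@consensus)
  if (length(object@meth) != len || length(object@unmeth) != len)
    msg <- c(msg, "count arrays must have one entry per consensus position")
  if (any(object@meth < 0) || any(object@unmeth < 0))
    msg <- c(msg, "counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Fraction methylated per consensus position
#'
#' @param object A [ConsensusProfile-class].
#' @return Numeric vector, one value per 0-based consensus position; `NA`
#'   where coverage is zero.
#' @export
profileFraction <- function(object) {
  cov <- object@meth + object@unmeth
  ifelse(cov > 0, object@meth / cov, NA_real_)
}

#' Coverage per consensus position
#' @param object A [ConsensusProfile-class].
#' @return Numeric vector of weighted coverage per position.
#' @export
profileCoverage <- function(object) object@meth + object@unmeth

setMethod("show", "ConsensusProfile", function(object) {
  cov <- profileCoverage(object)
  fr <- profileFraction(object)
  cat("ConsensusProfile [", object@family, "]: ", nchar(object@consensus),
      " bp, ", sum(cov > 0), " covered positions, mean fraction ",
      format(mean(fr, na.rm = TRUE), digits = 4), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## PipelineConfig
## ---------------------------------------------------------------------------

#' End-to-end analysis settings
#'
#' All tunables of the occupancy/methylation pipeline, with defaults set
#' to the published analysis settings: a 116 bp peak shift and 300 bp
#' scanning window; enriched regions thresholded at phred Q-value 20 (70
#' for per-element scoring), empirical FDR 13 and log2 ratio 1;
#' methylation windows of 10 CpGs requiring 10 observations per library,
#' reported at phred FDR 13 with no log2-ratio floor; up to 7 genomic and
#' 14 consensus alignments per read; a 100 N consensus spacer; 2%
#' spike-in; and 25-element moving-average blocks.
#'
#' @slot peakShift numeric, ChIP fragment shift (bp).
#' @slot windowSize,windowStep numeric, occupancy scanning window and step
#'   (bp).
#' @slot qThresholdRegions,qThresholdElements numeric, phred Q-value
#'   thresholds for region calling and per-element scoring.
#' @slot efdrThreshold numeric, phred empirical-FDR threshold.
#' @slot log2Threshold numeric, minimum log2 ChIP/input ratio.
#' @slot methWindowCpgs,methMinObs integer, CpGs per methylation window
#'   and minimum observations per library.
#' @slot methFdrThreshold,methLog2Threshold numeric, reporting thresholds
#'   for methylation windows.
#' @slot genomeMaxAlignments,consensusMaxAlignments integer, multi-mapper
#'   caps for genomic and consensus alignment.
#' @slot consensusSpacer integer, N spacer in the consensus index.
#' @slot spikeInFraction numeric, expected spike-in proportion.
#' @slot movingAverageBlock integer, elements per moving-average block.
#' @slot seed integer RNG seed for the pipeline run.
#' @seealso [pipelineConfig()], [runPipeline()]
#' @export
setClass("PipelineConfig",
  representation(peakShift = "numeric", windowSize = "numeric",
                 windowStep = "numeric",
                 qThresholdRegions = "numeric", qThresholdElements = "numeric",
                 efdrThreshold = "numeric", log2Threshold = "numeric",
                 methWindowCpgs = "integer", methMinObs = "integer",
                 methFdrThreshold = "numeric", methLog2Threshold = "numeric",
                 genomeMaxAlignments = "integer",
                 consensusMaxAlignments = "integer",
                 consensusSpacer = "integer", spikeInFraction = "numeric",
                 movingAverageBlock = "integer", seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- character(0)
  if (object@windowSize <= 0 || object@windowStep <= 0)
    msg <- c(msg, "windowSize and windowStep must be positive")
  if (object@methWindowCpgs < 1L || object@methMinObs < 0L)
    msg <- c(msg, "methylation window settings must be positive")
  if (object@genomeMaxAlignments < 1L || object@consensusMaxAlignments < 1L)
    msg <- c(msg, "alignment caps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Create pipeline settings
#'
#' Constructor for [PipelineConfig-class]; every published default can be
#' overridden.
#'
#' @param peakShift,windowSize,windowStep Occupancy scan geometry (bp).
#' @param qThresholdRegions,qThresholdElements,efdrThreshold,log2Threshold
#'   Occupancy thresholds (phred FDR scales and log2 ratio).
#' @param methWindowCpgs,methMinObs,methFdrThreshold,methLog2Threshold
#'   Methylation window test settings.
#' @param genomeMaxAlignments,consensusMaxAlignments Multi-mapper caps.
#' @param consensusSpacer N spacer length in the consensus index.
#' @param spikeInFraction Expected spike-in read proportion.
#' @param movingAverageBlock Elements per moving-average block.
#' @param seed Integer RNG seed.
#' @return A validated [PipelineConfig-class].
#' @examples
#' pipelineConfig()
#' @export
pipelineConfig <- function(peakShift = 116, windowSize = 300,
                           windowStep = windowSize / 2,
                           qThresholdRegions = 20, qThresholdElements = 70,
                           efdrThreshold = 13, log2Threshold = 1,
                           methWindowCpgs = 10L, methMinObs = 10L,
                           methFdrThreshold = 13, methLog2Threshold = 0,
                           genomeMaxAlignments = 7L,
                           consensusMaxAlignments = 14L,
                           consensusSpacer = 100L, spikeInFraction = 0.02,
                           movingAverageBlock = 25L, seed = 1L) {
  new("PipelineConfig", peakShift = peakShift, windowSize = windowSize,
      windowStep = windowStep, qThresholdRegions = qThresholdRegions,
      qThresholdElements = qThresholdElements,
      efdrThreshold = efdrThreshold, log2Threshold = log2Threshold,
      methWindowCpgs = as.integer(methWindowCpgs),
      methMinObs = as.integer(methMinObs),
      methFdrThreshold = methFdrThreshold,
      methLog2Threshold = methLog2Threshold,
      genomeMaxAlignments = as.integer(genomeMaxAlignments),
      consensusMaxAlignments = as.integer(consensusMaxAlignments),
      consensusSpacer = as.integer(consensusSpacer),
      spikeInFraction = spikeInFraction,
      movingAverageBlock = as.integer(movingAverageBlock),
      seed = as.integer(seed))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig: shift ", object@peakShift, " bp, window ",
      object@windowSize, "/", object@windowStep, " bp; thresholds Q ",
      object@qThresholdRegions, "/", object@qThresholdElements, ", eFDR ",
      object@efdrThreshold, ", log2 ", object@log2Threshold, "\n",
      "  meth windows: ", object@methWindowCpgs, " CpGs, min obs ",
      object@methMinObs, ", FDR ", object@methFdrThreshold,
      "; caps ", object@genomeMaxAlignments, "/",
      object@consensusMaxAlignments, "; seed ", object@seed, "\n", sep = "")
})

# Flatten a PipelineConfig (or SimConfig) to a plain named list, for the
# machine-readable config echo written with every run.
configToList <- function(object) {
  sn <- slotNames(class(object))
  setNames(lapply(sn, function(s) slot(object, s)), sn)
}
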