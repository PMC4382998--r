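## End-to-end driver: chain simulation (or real inputs) -> methylation
## calling -> occupancy scan -> differential methylation -> consensus
## profiles -> family statistics, writing every result table plus a
## machine-readable run report.

grToDf <- function(gr) {
  df <- as.data.frame(gr)
  names(df)[names(df) == "seqnames"] <- "contig"
  df$start <- df$start - 1L   # back to 0-based half-open for output
  df
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full ChIP-BS-Seq analysis pipeline
#'
#' Executes every stage over either a simulated experiment
#' (`simConfig` given) or real inputs (SAM alignments for ChIP and
#' input, genome FASTA, BED6+2 annotation, consensus FASTA): multi-mapper
#' weighted alignment loading, per-cytosine methylation calling with
#' spike-in conversion estimation, occupancy window scanning with
#' Q-value/empirical-FDR control, region calling and annotation
#' intersection, per-element occupancy scoring, methylation window and
#' element tests, percent-methylation scoring, consensus realignment
#' profiles for ChIP and input, family-level Kruskal-Wallis/Dunn
#' comparisons and the occupancy-vs-methylation moving-average curve.
#' All result tables, a config echo and a run report are written to
#' `outdir`; a rerun with the same configuration and seed reproduces
#' identical files.
#'
#' @param outdir Output directory (created).
#' @param simConfig A [SimConfig-class] to simulate inputs, or `NULL`.
#' @param chipSam,inputSam,genomeFasta,annotationBed,consensusFasta
#'   Paths to real inputs (used when `simConfig` is `NULL`).
#' @param config A [PipelineConfig-class] of analysis settings.
#' @param spikeContig Name of the unmethylated spike-in contig.
#' @return Invisibly, a list with every intermediate and final object
#'   (`calls`, `conversion`, `windows`, `regions`, `classCounts`,
#'   `elementScores`, `methWindows`, `methElements`,
#'   `fractionSignificant`, `profiles`, `familySummary`, `curve`, ...).
#' @examples
#' \dontrun{
#' res <- runPipeline(tempfile(), simConfig = simConfig(chipDepth = 5000L,
#'                    inputDepth = 5000L, seed = 11L))
#' res$fractionSignificant
#' }
#' @export
runPipeline <- function(outdir, simConfig = NULL,
                        chipSam = NULL, inputSam = NULL,
                        genomeFasta = NULL, annotationBed = NULL,
                        consensusFasta = NULL,
                        config = pipelineConfig(),
                        spikeContig = "spike") {
  validObject(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) message("[chipbs] ", ...)

  ## ---- inputs ------------------------------------------------------------
  if (!is.null(simConfig)) {
    log("simulating experiment (seed ", simConfig@seed, ")")
    simRes <- simulateExperiment(simConfig, file.path(outdir, "sim"))
    genome <- simRes$toy$genome
    annotation <- simRes$toy$annotation
    consensi <- simRes$toy$consensi
    chipRecords <- simRes$sim$chip$records
    inputRecords <- simRes$sim$input$records
  } else {
    if (is.null(chipSam) || is.null(inputSam) || is.null(genomeFasta) ||
        is.null(annotationBed))
      stop("either simConfig or chipSam/inputSam/genomeFasta/annotationBed ",
           "must be provided")
    genome <- Biostrings::readDNAStringSet(genomeFasta)
    names(genome) <- vapply(strsplit(names(genome), "\\s+"), `[[`, "", 1L)
    annotation <- readBedAnnotation(annotationBed)
    consensi <- if (!is.null(consensusFasta))
      readConsensusFasta(consensusFasta) else NULL
    chipRecords <- readSam(chipSam)
    inputRecords <- readSam(inputSam)
    simRes <- NULL
  }

  ## ---- methylation calling + conversion control --------------------------
  chipAln <- parseAlignments(chipRecords, config@genomeMaxAlignments)
  inputAln <- parseAlignments(inputRecords, config@genomeMaxAlignments)
  log("alignments: chip ", nrow(chipAln), " records (",
      attr(chipAln, "dropped"), " reads over cap), input ", nrow(inputAln),
      " records (", attr(inputAln, "dropped"), " over cap)")
  chipCalls <- callCytosines(chipAln, genome)
  inputCalls <- callCytosines(inputAln, genome)
  conversion <- list(
    chip = estimateConversion(chipCalls, spikeContig),
    input = estimateConversion(inputCalls, spikeContig))
  log(sprintf("conversion rates: chip %.4f, input %.4f",
              conversion$chip$rate, conversion$input$rate))
  writeCalls(chipCalls, file.path(outdir, "chip"))
  writeCalls(inputCalls, file.path(outdir, "input"))
  writeTsv(data.frame(library = c("chip", "input"),
                      converted = c(conversion$chip$converted,
                                    conversion$input$converted),
                      total = c(conversion$chip$total,
                                conversion$input$total),
                      rate = c(conversion$chip$rate,
                               conversion$input$rate)),
           file.path(outdir, "conversion.tsv"))

  ## ---- occupancy ---------------------------------------------------------
  contigLengths <- setNames(Biostrings::width(genome), names(genome))
  attr(chipAln, "contigLengths") <- contigLengths
  attr(inputAln, "contigLengths") <- contigLengths
  chipPd <- toPointData(chipAln, config@peakShift)
  inputPd <- toPointData(inputAln, config@peakShift)
  windows <- scanWindows(chipPd, inputPd, config@windowSize,
                         config@windowStep)
  swapped <- scanWindows(inputPd, chipPd, config@windowSize,
                         config@windowStep)
  windows <- attachFDR(windows, swapped)
  regions <- makeRegions(windows, config@qThresholdRegions,
                         config@efdrThreshold, config@log2Threshold)
  isect <- intersectAnnotation(regions, annotation)
  elementScores <- scoreElements(annotation, chipPd, inputPd,
                                 config@qThresholdElements)
  log(length(windows), " tested windows, ", length(regions),
      " enriched regions, ", sum(mcols(isect$elements)$enriched),
      " enriched elements")
  writeTsv(grToDf(windows), file.path(outdir, "windows.tsv"))
  writeTsv(grToDf(regions), file.path(outdir, "regions.tsv"))
  writeTsv(isect$classCounts, file.path(outdir, "enriched_by_class.tsv"))
  writeTsv(grToDf(elementScores), file.path(outdir, "element_scores.tsv"))

  ## ---- differential methylation ------------------------------------------
  methWindows <- testMethylationWindows(
    chipCalls, inputCalls, config@methWindowCpgs, config@methMinObs,
    config@methFdrThreshold, config@methLog2Threshold)
  methElements <- testMethylationElements(
    annotation, chipCalls, inputCalls, minObs = config@methMinObs,
    fdrThresh = config@methFdrThreshold)
  fracSig <- fractionSignificant(methElements)
  percentMeth <- scoreRegionMethylation(annotation, inputCalls)
  log(length(methWindows), " methylation windows tested, ",
      sum(mcols(methWindows)$reported), " reported")
  writeTsv(grToDf(methWindows), file.path(outdir, "meth_windows.tsv"))
  writeTsv(grToDf(methElements), file.path(outdir, "meth_elements.tsv"))
  writeTsv(fracSig, file.path(outdir, "fraction_significant.tsv"))
  writeTsv(grToDf(percentMeth), file.path(outdir, "percent_meth.tsv"))

  ## ---- consensus profiles ------------------------------------------------
  profiles <- list()
  if (!is.null(consensi) && length(consensi)) {
    index <- consensusIndex(consensi, config@consensusSpacer)
    for (lib in c("chip", "input")) {
      aln <- if (lib == "chip") chipAln else inputAln
      reads <- selectRepeatReads(aln, annotation, "SINE")
      profiles[[lib]] <- profileReads(
        reads, index, maxAlignments = config@consensusMaxAlignments)
      if (length(profiles[[lib]]))
        writeProfiles(profiles[[lib]],
                      file.path(outdir, paste0(lib, "_consensus")))
      log(lib, ": ", length(reads), " repeat reads profiled on ",
          length(profiles[[lib]]), " consensi")
    }
  }

  ## ---- family statistics -------------------------------------------------
  joined <- elementScores
  mcols(joined)$percent_meth <- mcols(percentMeth)$percent_meth
  sine <- joined[mcols(joined)$class == "SINE" &
                 !mcols(joined)$zero_coverage]
  famSummary <- NULL
  curve <- NULL
  if (length(unique(mcols(sine)$family)) >= 2L) {
    famSummary <- familySummary(sine)
    writeTsv(famSummary$table, file.path(outdir, "family_summary.tsv"))
    if (!is.null(famSummary$kwMethylation)) {
      kw <- famSummary$kwMethylation
      writeTsv(data.frame(axis = c("occupancy", "methylation"),
                          H = c(famSummary$kwOccupancy$H, kw$H),
                          df = c(famSummary$kwOccupancy$df, kw$df),
                          p_value = c(famSummary$kwOccupancy$p_value,
                                      kw$p_value)),
               file.path(outdir, "family_kw.tsv"))
      writeTsv(rbind(cbind(axis = "occupancy",
                           as.data.frame(famSummary$dunnOccupancy)),
                     cbind(axis = "methylation",
                           as.data.frame(famSummary$dunnMethylation))),
               file.path(outdir, "family_dunn.tsv"))
    }
  }
  ok <- !is.na(mcols(sine)$percent_meth)
  if (sum(ok) >= config@movingAverageBlock) {
    curve <- movingAverageCurve(mcols(sine)$percent_meth[ok],
                                mcols(sine)$occupancy_score[ok],
                                config@movingAverageBlock)
    writeTsv(curve, file.path(outdir, "moving_average_curve.tsv"))
  }

  ## ---- run report ---------------------------------------------------------
  report <- list(
    package = as.character(packageVersion("chipbs")),
    r_version = R.version.string,
    seed = if (!is.null(simConfig)) simConfig@seed else config@seed,
    config = lapply(configToList(config), unname),
    sim_config = if (!is.null(simConfig))
      lapply(configToList(simConfig), unname) else NULL,
    counters = list(
      chip_records = nrow(chipAln), input_records = nrow(inputAln),
      chip_reads_dropped = attr(chipAln, "dropped"),
      input_reads_dropped = attr(inputAln, "dropped"),
      windows_tested = length(windows),
      regions = length(regions),
      meth_windows_tested = length(methWindows)),
    conversion = list(chip = conversion$chip$rate,
                      input = conversion$input$rate))
  yaml::write_yaml(report, file.path(outdir, "run_report.yaml"))

  invisible(list(
    genome = genome, annotation = annotation, sim = simRes,
    chipAln = chipAln, inputAln = inputAln,
    chipCalls = chipCalls, inputCalls = inputCalls,
    conversion = conversion,
    windows = windows, regions = regions,
    classCounts = isect$classCounts, enrichedElements = isect$elements,
    elementScores = elementScores,
    methWindows = methWindows, methElements = methElements,
    fractionSignificant = fracSig, percentMeth = percentMeth,
    profiles = profiles, familySummary = famSummary, curve = curve,
    outdir = outdir))
}
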