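## Occupancy analysis: point-data conversion, sliding-window enrichment
## scan with Q-value and empirical FDR, region making, annotation
## intersection and per-element scoring.

#' Convert alignment records to single-position point data
#'
#' Each alignment record is collapsed to one genomic point shifted
#' towards the fragment midpoint: plus-strand records contribute a point
#' at `start + peakShift/2`, minus-strand records at `end - peakShift/2`
#' (0-based), with the record's multi-mapper weight preserved and points
#' clipped to the contig bounds. The peak shift is the fragment-length
#' offset determined upstream (116 bp for the published libraries).
#'
#' @param records Weighted alignment table from [parseAlignments()].
#' @param peakShift Shift in bp.
#' @param contigLengths Named numeric of contig lengths; defaults to the
#'   attribute carried by `records`.
#' @return A [PointData-class] object.
#' @examples
#' \dontrun{pd <- toPointData(parseAlignments("chip.sam"), peakShift = 116)}
#' @export
toPointData <- function(records, peakShift = 116,
                        contigLengths = attr(records, "contigLengths")) {
  if (is.null(contigLengths))
    stop("contigLengths required (none attached to records)")
  readLen <- nchar(records$seq)
  point <- ifelse(records$strand == "+",
                  records$start + peakShift / 2,
                  records$start + readLen - peakShift / 2)
  point <- pmin(pmax(point, 0), contigLengths[records$contig] - 1)
  positions <- split(point, records$contig)
  weights <- split(records$weight, records$contig)
  ## keep all contigs, even empty ones, in contigLengths order
  ctg <- names(contigLengths)
  positions <- setNames(lapply(ctg, function(x)
    as.numeric(positions[[x]])), ctg)
  weights <- setNames(lapply(ctg, function(x)
    as.numeric(weights[[x]])), ctg)
  new("PointData", positions = positions, weights = weights,
      librarySize = sum(records$weight), peakShift = peakShift,
      contigLengths = contigLengths)
}

# One-sided binomial enrichment p-value on rounded weighted counts:
# chip successes among chip+input trials against the library-size null.
binomEnrichP <- function(chipSum, inputSum, p0) {
  k <- roundHalfUp(chipSum)
  n <- k + roundHalfUp(inputSum)
  p <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  p[n == 0] <- 1
  p
}

# Library-size-normalised log2 ratio with pseudocount 0.5 on both sides.
log2Enrich <- function(chipSum, inputSum, chipLib, inputLib) {
  meanLib <- (chipLib + inputLib) / 2
  log2((chipSum * meanLib / chipLib + 0.5) /
       (inputSum * meanLib / inputLib + 0.5))
}

#' Scan the genome in sliding windows for occupancy enrichment
#'
#' Slides fixed-width windows along every contig and, for each window,
#' sums ChIP and input point weights, computes the library-size
#' normalised log2 ratio (pseudocount 0.5), and a one-sided binomial
#' enrichment p-value: rounded chip counts as successes among
#' chip+input trials with success probability
#' `librarySize(chip) / (librarySize(chip) + librarySize(input))`.
#' Windows with no points in either library are omitted.
#'
#' @param chip,input [PointData-class] objects for the two libraries.
#' @param windowSize Window width in bp (default 300).
#' @param step Step between window starts (default `windowSize/2`).
#' @param normalized If `TRUE`, the binomial test uses library-size
#'   normalised (then rounded) counts with null probability 0.5 instead
#'   of raw counts with the library-size null.
#' @return A [GenomicRanges::GRanges] of tested windows with metadata
#'   columns `chip_sum`, `input_sum`, `log2_ratio` and `p_value`.
#' @seealso [attachFDR()], [makeRegions()]
#' @export
scanWindows <- function(chip, input, windowSize = 300,
                        step = windowSize / 2, normalized = FALSE) {
  if (windowSize <= 0 || step <= 0)
    stop("windowSize and step must be positive")
  if (librarySize(chip) <= 0 || librarySize(input) <= 0)
    stop("both libraries must contain points")
  res <- list()
  for (ctg in names(chip@positions)) {
    len <- chip@contigLengths[[ctg]]
    if (is.na(len) || len < windowSize) next
    starts <- seq(0, len - windowSize, by = step)
    cs <- weightedRangeSums(chip@positions[[ctg]], chip@weights[[ctg]],
                            starts, starts + windowSize)
    is <- weightedRangeSums(input@positions[[ctg]], input@weights[[ctg]],
                            starts, starts + windowSize)
    keep <- cs + is > 0
    if (!any(keep)) next
    res[[ctg]] <- data.frame(contig = ctg, start = starts[keep],
                             chip_sum = cs[keep], input_sum = is[keep])
  }
  if (!length(res)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(chip_sum = numeric(0), input_sum = numeric(0),
                           log2_ratio = numeric(0), p_value = numeric(0))
    return(gr)
  }
  df <- do.call(rbind, res)
  cl <- librarySize(chip); il <- librarySize(input)
  if (normalized) {
    meanLib <- (cl + il) / 2
    p <- binomEnrichP(df$chip_sum * meanLib / cl,
                      df$input_sum * meanLib / il, 0.5)
  } else {
    p <- binomEnrichP(df$chip_sum, df$input_sum, cl / (cl + il))
  }
  gr <- GRanges(df$contig, IRanges(df$start + 1L, width = windowSize),
                chip_sum = df$chip_sum, input_sum = df$input_sum,
                log2_ratio = log2Enrich(df$chip_sum, df$input_sum, cl, il),
                p_value = p)
  seqlengths(gr) <- chip@contigLengths[seqlevels(gr)]
  gr
}

#' Attach Q-value and empirical FDR to scanned windows
#'
#' The phred-scaled Q-value is `-10 log10` of the Benjamini-Hochberg
#' adjusted p-value over all tested windows. The empirical FDR at a
#' window with p-value p compares label-swapped and real scans:
#' `max(1, # swapped windows with p' <= p) / (# real windows with
#' p' <= p)`, phred-scaled and capped at 100. `swapped` must come from
#' re-running [scanWindows()] with the chip and input libraries
#' exchanged.
#'
#' @param windows [scanWindows()] output for the real orientation.
#' @param swapped [scanWindows()] output with libraries exchanged.
#' @return `windows` with added metadata columns `q_phred` and
#'   `efdr_phred`.
#' @export
attachFDR <- function(windows, swapped) {
  p <- mcols(windows)$p_value
  mcols(windows)$q_phred <- phredScale(p.adjust(p, method = "BH"))
  sp <- sort(mcols(swapped)$p_value)
  rp <- sort(p)
  nSwap <- findInterval(p, sp)          # swapped windows with p' <= p
  nReal <- findInterval(p, rp)          # real windows with p' <= p
  efdr <- pmin(1, pmax(1, nSwap) / pmax(1, nReal))
  ## monotone (q-value style) enforcement: a stronger window never gets a
  ## worse empirical FDR than any weaker one; without it the numerator
  ## floor of 1 would penalise exactly the top-ranked windows
  o <- order(p)
  efdr[o] <- rev(cummin(rev(efdr[o])))
  mcols(windows)$efdr_phred <- phredScale(efdr)
  windows
}

#' Merge passing windows into enriched regions
#'
#' Windows simultaneously passing the phred Q-value, phred empirical-FDR
#' and log2-ratio thresholds (defaults 20, 13, 1 - the published region
#' settings) are merged when overlapping or book-ended adjacent. Each
#' region records its best (lowest-p) window.
#'
#' @param windows Output of [attachFDR()].
#' @param qThresh,efdrThresh Minimum phred-scaled Q-value / empirical FDR.
#' @param log2Thresh Minimum log2 ChIP/input ratio.
#' @return A sorted, non-overlapping [GenomicRanges::GRanges] of regions
#'   with `n_windows`, `best_p`, `best_log2` and `best_q_phred`.
#' @export
makeRegions <- function(windows, qThresh = 20, efdrThresh = 13,
                        log2Thresh = 1) {
  mc <- mcols(windows)
  pass <- mc$q_phred >= qThresh & mc$efdr_phred >= efdrThresh &
    mc$log2_ratio >= log2Thresh
  hits <- windows[pass]
  if (!length(hits)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(n_windows = integer(0), best_p = numeric(0),
                           best_log2 = numeric(0), best_q_phred = numeric(0))
    return(gr)
  }
  regions <- reduce(granges(hits), ignore.strand = TRUE)
  ov <- findOverlaps(regions, hits)
  best <- tapply(seq_along(subjectHits(ov)), queryHits(ov), function(i) {
    j <- subjectHits(ov)[i]
    j[which.min(mcols(hits)$p_value[j])]
  })
  bestIdx <- as.integer(best)
  mcols(regions)$n_windows <- as.integer(table(queryHits(ov)))
  mcols(regions)$best_p <- mcols(hits)$p_value[bestIdx]
  mcols(regions)$best_log2 <- mcols(hits)$log2_ratio[bestIdx]
  mcols(regions)$best_q_phred <- mcols(hits)$q_phred[bestIdx]
  sort(regions)
}

#' Intersect enriched regions with an element annotation
#'
#' An element is called enriched when any region overlaps it by at least
#' 1 bp. Returns the flagged annotation together with per-class tallies
#' (the enriched-genes-by-class summary).
#'
#' @param regions [makeRegions()] output.
#' @param annotation Element [GenomicRanges::GRanges] with `class` (and
#'   `element_id`) metadata.
#' @return A list with `elements` (annotation plus logical `enriched`
#'   column) and `classCounts` (`data.frame` of class, n elements,
#'   n enriched).
#' @export
intersectAnnotation <- function(regions, annotation) {
  enriched <- countOverlaps(annotation, regions, ignore.strand = TRUE) > 0
  out <- annotation
  mcols(out)$enriched <- enriched
  cls <- mcols(annotation)$class
  tab <- data.frame(
    class = sort(unique(cls)),
    n_elements = as.integer(table(cls)[sort(unique(cls))]),
    n_enriched = as.integer(tapply(enriched, cls, sum)[sort(unique(cls))]))
  list(elements = out, classCounts = tab)
}

#' Score annotated elements for occupancy
#'
#' Applies the window statistic over each element's own span: weighted
#' ChIP and input sums, library-size normalised log2 occupancy score
#' (pseudocount 0.5), one-sided binomial p-value, and a
#' Benjamini-Hochberg phred Q-value across all covered elements.
#' Elements with no points in either library are flagged
#' `zero_coverage` and excluded from the multiple-testing family.
#'
#' @param annotation Element [GenomicRanges::GRanges].
#' @param chip,input [PointData-class] objects.
#' @param qThresh Phred Q-value above which an element is flagged
#'   `high_confidence` (default 70, the published per-element setting).
#' @return The annotation with added metadata columns `chip_sum`,
#'   `input_sum`, `occupancy_score`, `p_value`, `q_phred`,
#'   `zero_coverage` and `high_confidence`.
#' @export
scoreElements <- function(annotation, chip, input, qThresh = 70) {
  cl <- librarySize(chip); il <- librarySize(input)
  cs <- numeric(length(annotation)); is <- numeric(length(annotation))
  for (ctg in unique(as.character(seqnames(annotation)))) {
    sel <- which(as.character(seqnames(annotation)) == ctg)
    s0 <- start(annotation)[sel] - 1L
    e0 <- end(annotation)[sel]
    if (!is.null(chip@positions[[ctg]]))
      cs[sel] <- weightedRangeSums(chip@positions[[ctg]],
                                   chip@weights[[ctg]], s0, e0)
    if (!is.null(input@positions[[ctg]]))
      is[sel] <- weightedRangeSums(input@positions[[ctg]],
                                   input@weights[[ctg]], s0, e0)
  }
  zero <- cs + is == 0
  p <- binomEnrichP(cs, is, cl / (cl + il))
  p[zero] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[!zero] <- phredScale(p.adjust(p[!zero], method = "BH"))
  out <- annotation
  mcols(out)$chip_sum <- cs
  mcols(out)$input_sum <- is
  mcols(out)$occupancy_score <- log2Enrich(cs, is, cl, il)
  mcols(out)$p_value <- p
  mcols(out)$q_phred <- q
  mcols(out)$zero_coverage <- zero
  mcols(out)$high_confidence <- !zero & q >= qThresh
  out
}
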