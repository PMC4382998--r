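## Per-cytosine methylation calling from bisulphite alignments, with
## multi-mapper weighting and spike-in conversion-rate estimation.

#' Load alignments and assign multi-mapper weights
#'
#' Reads a SAM file (or takes an alignment table from [readSam()]) and
#' attaches the 1/k multi-mapper weight to every placement: a read
#' reported at k locations contributes k records of weight 1/k, so the
#' total weight per kept read is exactly 1. Reads with more placements
#' than `maxAlignments` are dropped entirely and counted; unmapped
#' records were already skipped by the reader.
#'
#' The default cap of 7 follows the repeat-rescue alignment strategy for
#' SINE-dense genomes (report up to seven locations per repeat read);
#' `weightScheme = "unit"` gives every placement weight 1 for sensitivity
#' analysis.
#'
#' @param sam Path to a SAM file, or a `data.frame` from [readSam()].
#' @param maxAlignments Integer cap on reported placements per read.
#' @param weightScheme `"1/k"` (default, conserves read counts) or
#'   `"unit"`.
#' @return The alignment `data.frame` with a `weight` column; attributes
#'   `dropped` (reads removed by the cap) and `contigLengths` are
#'   attached.
#' @seealso [callCytosines()], [toPointData()]
#' @export
parseAlignments <- function(sam, maxAlignments = 7L,
                            weightScheme = c("1/k", "unit")) {
  weightScheme <- match.arg(weightScheme)
  rec <- if (is.character(sam)) readSam(sam) else sam
  contigLengths <- attr(rec, "contigLengths")
  if (!nrow(rec)) {
    rec$weight <- numeric(0)
    attr(rec, "dropped") <- 0L
    attr(rec, "contigLengths") <- contigLengths
    return(rec)
  }
  ## placement count: NH tag when present, else observed records per read
  obs <- table(rec$read_id)
  k <- pmax(rec$n_alignments, as.integer(obs[rec$read_id]))
  keep <- k <= maxAlignments
  dropped <- length(unique(rec$read_id[!keep]))
  out <- rec[keep, , drop = FALSE]
  out$n_alignments <- k[keep]
  out$weight <- if (weightScheme == "1/k") 1 / out$n_alignments else 1
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "contigLengths") <- contigLengths
  out
}

#' Call per-cytosine methylation from bisulphite alignments
#'
#' Converts weighted alignment records into per-cytosine methylated and
#' unmethylated observation counts. For original-top-strand (OT) reads,
#' every reference plus-strand C covered by the read is inspected: a read
#' base C adds the record's weight to the methylated count, T to the
#' unmethylated count, and any other base (a sequencing error) is
#' ignored. Original-bottom-strand (OB) reads are handled symmetrically
#' at reference minus-strand cytosines (reference G on the plus strand:
#' read base G = methylated, A = unmethylated). The cytosine context
#' (CpG/CHG/CHH) is assigned from the reference on the cytosine's own
#' strand. No base-quality filtering is applied, so repeat alignments
#' contribute fully.
#'
#' Calls are indexed by the cytosine's position in plus-strand
#' coordinates with a strand column; the two cytosines of one CpG are
#' not pooled unless `poolCpG = TRUE`, which merges each symmetric CpG
#' pair onto its plus-strand C.
#'
#' @param records Weighted alignment table from [parseAlignments()].
#' @param genome A [Biostrings::DNAStringSet] covering all contigs in
#'   `records`.
#' @param poolCpG Logical; merge symmetric CpG pairs (default `FALSE`).
#' @return A [CytosineCalls-class] object. Records extending past the
#'   contig end are skipped and counted in attribute `skipped` of the
#'   object's metadata.
#' @examples
#' cfg <- simConfig(genomeLength = 30000L, copiesPerFamily = 8L,
#'                  chipDepth = 300L, inputDepth = 300L, seed = 5L)
#' toy <- buildToyGenome(cfg)
#' sim <- simulateReads(cfg, toy)
#' calls <- callCytosines(parseAlignments(sim$input$records), toy$genome)
#' calls
#' @export
callCytosines <- function(records, genome, poolCpG = FALSE) {
  contigs <- names(genome)
  if (!all(records$contig %in% contigs))
    stop("reference does not cover contigs: ",
         paste(setdiff(records$contig, contigs), collapse = ", "))
  chars <- lapply(contigs, function(ctg)
    strsplit(as.character(genome[[ctg]]), "")[[1]])
  names(chars) <- contigs
  clen <- vapply(chars, length, integer(1))

  readLen <- nchar(records$seq)
  over <- records$start + readLen > clen[records$contig] | records$start < 0
  skipped <- sum(over)
  if (skipped) {
    warning(skipped, " record(s) extend past the contig end; skipped")
    records <- records[!over, , drop = FALSE]
    readLen <- readLen[!over]
  }
  if (!nrow(records)) {
    calls <- newCytosineCalls(data.table::data.table(
      contig = character(0), pos = integer(0), strand = character(0),
      meth = numeric(0), unmeth = numeric(0)), chars, skipped)
    return(calls)
  }

  ## long table: one row per (record, covered base)
  n <- nrow(records)
  RL <- readLen
  rows <- rep.int(seq_len(n), RL)
  off <- unlist(lapply(RL, seq_len), use.names = FALSE) - 1L
  pos <- records$start[rows] + off
  readChar <- unlist(strsplit(records$seq, "", fixed = TRUE),
                     use.names = FALSE)
  ## reference base at each covered position
  ctgIdx <- match(records$contig, contigs)[rows]
  refChar <- character(length(pos))
  for (ci in unique(ctgIdx)) {
    sel <- ctgIdx == ci
    refChar[sel] <- chars[[ci]][pos[sel] + 1L]
  }
  ot <- records$bs_strand[rows] == "OT"
  wt <- records$weight[rows]

  isC <- ot & refChar == "C"
  isG <- !ot & refChar == "G"
  status <- rep(NA_integer_, length(pos))  # 1 = meth, 0 = unmeth
  status[isC & readChar == "C"] <- 1L
  status[isC & readChar == "T"] <- 0L
  status[isG & readChar == "G"] <- 1L
  status[isG & readChar == "A"] <- 0L
  keep <- !is.na(status)

  dt <- data.table::data.table(
    contig = records$contig[rows][keep],
    pos = pos[keep],
    strand = ifelse(ot[keep], "+", "-"),
    meth = wt[keep] * (status[keep] == 1L),
    unmeth = wt[keep] * (status[keep] == 0L))
  agg <- dt[, list(meth = sum(meth), unmeth = sum(unmeth)),
            by = c("contig", "pos", "strand")]
  data.table::setorderv(agg, c("contig", "pos", "strand"))
  newCytosineCalls(agg, chars, skipped, poolCpG = poolCpG)
}

# Assemble a CytosineCalls object from an aggregated count table,
# attaching sequence context from the reference.
newCytosineCalls <- function(agg, chars, skipped, poolCpG = FALSE) {
  context <- character(nrow(agg))
  if (nrow(agg)) {
    for (ctg in unique(agg$contig)) {
      sel <- which(agg$contig == ctg)
      context[sel] <- cytosineContext(chars[[ctg]], agg$pos[sel],
                                      agg$strand[sel])
    }
  }
  gr <- GRanges(agg$contig, IRanges(agg$pos + 1L, width = 1L),
                strand = agg$strand, context = context,
                meth = agg$meth, unmeth = agg$unmeth)
  seqlengths(gr) <- vapply(chars, length, integer(1))[seqlevels(gr)]
  if (poolCpG) gr <- poolSymmetricCpgs(gr)
  calls <- new("CytosineCalls", gr)
  metadata(calls)$skipped <- skipped
  calls
}

# Context of a cytosine on its own strand, from plus-strand reference
# characters: CpG = next base G; CHG = next-next base G; else CHH.
# For minus-strand cytosines "next" walks leftwards in complement space.
cytosineContext <- function(chars, pos, strand) {
  L <- length(chars)
  n1 <- ifelse(strand == "+", pos + 2L, pos)      # 1-based next base
  n2 <- ifelse(strand == "+", pos + 3L, pos - 1L)
  b1 <- ifelse(n1 >= 1L & n1 <= L, chars[pmin(pmax(n1, 1L), L)], "N")
  b2 <- ifelse(n2 >= 1L & n2 <= L, chars[pmin(pmax(n2, 1L), L)], "N")
  want <- ifelse(strand == "+", "G", "C")  # G on own strand
  ifelse(b1 == want, "CpG", ifelse(b2 == want, "CHG", "CHH"))
}

# Merge the two calls of a symmetric CpG pair onto the plus-strand C.
poolSymmetricCpgs <- function(gr) {
  std <- as.character(strand(gr))
  isCpG <- mcols(gr)$context == "CpG"
  minus <- isCpG & std == "-"
  key <- paste0(as.character(seqnames(gr)), ":",
                start(gr) - ifelse(minus, 1L, 0L))
  keep <- !(minus & key %in% key[isCpG & std == "+"])
  dt <- data.table::data.table(site = key, meth = mcols(gr)$meth,
                               unmeth = mcols(gr)$unmeth)
  sums <- dt[, list(meth = sum(meth), unmeth = sum(unmeth)), by = "site"]
  out <- gr[keep]
  i <- match(key[keep], sums$site)
  mcols(out)$meth <- sums$meth[i]
  mcols(out)$unmeth <- sums$unmeth[i]
  out
}

#' Estimate the bisulphite conversion rate from the spike-in
#'
#' All cytosines of the spike-in contig are truly unmethylated, so every
#' retained C there is a conversion failure. The conversion rate is the
#' weighted fraction of spike-in cytosine observations read as converted,
#' pooled over all sequence contexts.
#'
#' @param calls A [CytosineCalls-class] object.
#' @param spikeContig Name of the spike-in contig (default `"spike"`).
#' @return A list of class `ConversionEstimate` with `converted`,
#'   `total` (weighted counts) and `rate`.
#' @examples
#' \dontrun{estimateConversion(calls, "spike")}
#' @export
estimateConversion <- function(calls, spikeContig = "spike") {
  sel <- as.character(seqnames(calls)) == spikeContig
  total <- sum(callCoverage(calls)[sel])
  if (total <= 0)
    stop("no conversion control: zero coverage on spike-in contig '",
         spikeContig, "'")
  converted <- sum(unmethCount(calls)[sel])
  structure(list(converted = converted, total = total,
                 rate = converted / total),
            class = "ConversionEstimate")
}

#' @export
print.ConversionEstimate <- function(x, ...) {
  cat(sprintf(
    "Bisulphite conversion: %.4f%% (%0.1f of %0.1f weighted C observations converted)\n",
    100 * x$rate, x$converted, x$total))
  invisible(x)
}
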