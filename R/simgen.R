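## Synthetic ChIP-BS-Seq data: toy genomes with repeat families, methylation
## truth, occupancy truth, and bisulphite-converted reads with spike-in.

BASES <- c("A", "C", "G", "T")

randomDna <- function(n, gc = 0.42) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(BASES, n, replace = TRUE, prob = p)
}

# Overwrite random dinucleotide slots with CG until the consensus holds
# roughly `target` CpGs; slots are spaced >= 2 apart so injections do not
# overlap each other.
injectCpgs <- function(chars, target) {
  if (target <= 0) return(chars)
  len <- length(chars)
  slots <- seq(1L, len - 1L, by = 3L)
  pick <- sample(slots, min(target, length(slots)))
  chars[pick] <- "C"
  chars[pick + 1L] <- "G"
  chars
}

# Remove every CpG whose C (plus or minus strand) falls inside
# [start, end) (0-based); used for zero-CpG-density families. Replacing
# with A/T can never create a new CG dinucleotide.
scrubCpgs <- function(chars, start, end) {
  lo <- max(1L, start)           # 1-based index of first base to inspect
  hi <- min(length(chars), end + 1L)
  idx <- seq(lo, hi - 1L)
  cg <- idx[chars[idx] == "C" & chars[idx + 1L] == "G"]
  for (p in cg) {
    if (p >= start + 1L && p <= end)        chars[p] <- "T"   # C inside
    if (p + 1L >= start + 1L && p + 1L <= end) chars[p + 1L] <- "A" # G inside
  }
  chars
}

mutateSeq <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    sub <- vapply(chars[hit],
                  function(b) sample(setdiff(BASES, b), 1L), "")
    chars[hit] <- sub
  }
  chars
}

#' Build a synthetic genome with repeat families and methylation truth
#'
#' Constructs a toy genome for ChIP-BS-Seq simulation: a main contig
#' carrying `nFamilies` SINE-like repeat families (each with a stored
#' consensus, copies mutated at `familyDivergence`, and at least one
#' exact-duplicate copy pair per family so that multi-mapping reads
#' arise), a set of short CpG-poor tRNA-gene-like loci, and a fully
#' unmethylated spike-in contig. Every CpG in the genome is recorded on
#' both strands in the truth table with its methylation probability:
#' family-specific inside SINE elements, `trnaMethProb` at tRNA-like
#' loci, `backgroundMethProb` elsewhere on the main contig, and 0 on the
#' spike-in.
#'
#' @param config A [SimConfig-class] object.
#' @return A list with components:
#' \describe{
#'   \item{genome}{[Biostrings::DNAStringSet] of the main contig
#'     (`chrT`) and the spike-in contig (`spike`).}
#'   \item{annotation}{[GenomicRanges::GRanges] of elements with
#'     `element_id`, `family`, `class`, `dup_group` and `dup_size`.}
#'   \item{cpgTable}{`data.frame` (`contig`, `pos` 0-based, `strand`,
#'     `meth_prob`): one row per CpG cytosine per strand.}
#'   \item{consensi}{Named [Biostrings::DNAStringSet] of SINE family
#'     consensus sequences (the consensus-index input).}
#' }
#' @examples
#' toy <- buildToyGenome(simConfig(genomeLength = 30000L,
#'                                 copiesPerFamily = 8L, seed = 3L))
#' toy$annotation
#' @export
buildToyGenome <- function(config) {
  validObject(config)
  set.seed(config@seed)
  nFam <- config@nFamilies
  famNames <- c("AluY-like", "AluS-like", "AluJ-like",
                sprintf("FAM%d", seq_len(max(0L, nFam - 3L)) + 3L))[seq_len(nFam)]
  trnaLen <- 75L

  ## family consensi (SINE families), plus one tRNA-like consensus
  consensi <- lapply(seq_len(nFam), function(i) {
    ch <- randomDna(config@elementLength, gc = 0.55)
    ch <- scrubCpgs(ch, 0L, config@elementLength)
    injectCpgs(ch, round(config@cpgDensity[i] * config@elementLength / 100))
  })
  trnaCons <- scrubCpgs(randomDna(trnaLen, gc = 0.6), 0L, trnaLen)
  trnaCons <- injectCpgs(trnaCons, 1L)

  ## element layout: SINE copies then tRNA loci, shuffled along the contig
  fam <- c(rep(seq_len(nFam), each = config@copiesPerFamily),
           rep(0L, config@nTrnaLoci))          # 0 = tRNA-like
  elemLen <- ifelse(fam == 0L, trnaLen, config@elementLength)
  nElem <- length(fam)
  free <- config@genomeLength - sum(elemLen)
  if (free < nElem + 1L)
    stop("genome too small for requested elements: need at least ",
         sum(elemLen) + nElem + 1L - config@genomeLength, " more bases")
  ord <- sample.int(nElem)
  fam <- fam[ord]; elemLen <- elemLen[ord]
  gaps <- floor(free * diff(c(0, sort(runif(nElem)), 1)))
  gaps[nElem + 1L] <- free - sum(gaps[seq_len(nElem)])
  starts <- cumsum(gaps[seq_len(nElem)]) + cumsum(c(0L, elemLen[-nElem]))

  ## copy sequences: per SINE family, copy 2 duplicates copy 1 exactly
  copyIdx <- integer(nElem)
  for (i in seq_len(nFam)) copyIdx[fam == i] <- seq_len(sum(fam == i))
  copyIdx[fam == 0L] <- seq_len(sum(fam == 0L))
  strandOf <- sample(c("+", "-"), nElem, replace = TRUE)
  copySeq <- vector("list", nElem)
  for (i in seq_len(nElem)) {
    if (fam[i] == 0L) {
      copySeq[[i]] <- mutateSeq(trnaCons, 0.10)
    } else if (copyIdx[i] == 2L) {
      j <- which(fam == fam[i] & copyIdx == 1L)
      copySeq[[i]] <- copySeq[[j]]
      strandOf[i] <- strandOf[j]
    } else {
      copySeq[[i]] <- mutateSeq(consensi[[fam[i]]], config@familyDivergence)
    }
  }

  ## assemble the main contig
  chars <- randomDna(config@genomeLength, gc = 0.40)
  for (i in seq_len(nElem)) {
    s <- copySeq[[i]]
    if (strandOf[i] == "-") s <- rev(chartr("ACGT", "TGCA", s))
    chars[(starts[i] + 1L):(starts[i] + elemLen[i])] <- s
  }
  for (i in which(fam > 0L)) {      # enforce zero-density families exactly
    if (config@cpgDensity[fam[i]] == 0)
      chars <- scrubCpgs(chars, starts[i], starts[i] + elemLen[i])
  }
  spikeChars <- randomDna(config@spikeInLength, gc = 0.48)
  genome <- Biostrings::DNAStringSet(c(
    chrT = paste(chars, collapse = ""),
    spike = paste(spikeChars, collapse = "")))

  ## annotation with duplicate groups (string identity of genome spans)
  famLabel <- ifelse(fam == 0L, "tDNA-like", famNames[pmax(fam, 1L)])
  classLabel <- ifelse(fam == 0L, "tRNA", config@familyClass[pmax(fam, 1L)])
  elementId <- sprintf("%s_%03d", famLabel, copyIdx)
  spanSeq <- vapply(seq_len(nElem), function(i)
    paste(chars[(starts[i] + 1L):(starts[i] + elemLen[i])], collapse = ""), "")
  dupKey <- paste0(famLabel, ":", spanSeq)
  dupGroup <- match(dupKey, unique(dupKey))
  dupSize <- as.integer(table(dupGroup)[as.character(dupGroup)])
  annotation <- GRanges("chrT",
                        IRanges(start = starts + 1L, width = elemLen),
                        strand = strandOf,
                        element_id = elementId, family = famLabel,
                        class = classLabel, dup_group = dupGroup,
                        dup_size = dupSize)
  seqlengths(annotation) <- c(chrT = config@genomeLength)

  ## CpG truth table, both strands, all contigs
  elemProb <- ifelse(fam == 0L, config@trnaMethProb,
                     config@methProb[pmax(fam, 1L)])
  cpgTable <- rbind(
    cpgRows(chars, "chrT", annotation, elemProb, config@backgroundMethProb),
    cpgRows(spikeChars, "spike", NULL, numeric(0), 0))
  list(genome = genome, annotation = annotation, cpgTable = cpgTable,
       consensi = Biostrings::DNAStringSet(
         setNames(vapply(consensi, paste, "", collapse = ""), famNames)))
}

# CpG truth rows for one contig: plus-strand C at p, minus-strand C at the
# G position p+1 (0-based), with the methylation probability of the
# element containing each cytosine (elemProb parallels the annotation).
cpgRows <- function(chars, contig, annotation, elemProb, bgProb) {
  p <- which(chars[-length(chars)] == "C" & chars[-1L] == "G")  # 1-based C
  if (!length(p))
    return(data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), meth_prob = numeric(0)))
  pos <- c(p - 1L, p)                      # 0-based: C then G position
  strand <- rep(c("+", "-"), each = length(p))
  prob <- rep(bgProb, length(pos))
  if (!is.null(annotation) && length(annotation)) {
    gr <- GRanges(contig, IRanges(pos + 1L, width = 1L))
    hit <- findOverlaps(gr, annotation, select = "first", ignore.strand = TRUE)
    inside <- !is.na(hit)
    prob[inside] <- elemProb[hit[inside]]
  }
  df <- data.frame(contig = contig, pos = pos, strand = strand,
                   meth_prob = prob)
  df[order(df$pos, df$strand), , drop = FALSE]
}

#' Simulate bisulphite-converted ChIP and input reads
#'
#' Samples sequencing fragments from the toy genome (uniformly for the
#' input library; with probability mass multiplied by `occupancyFold`
#' over the occupied loci, then renormalised, for the ChIP library),
#' assigns each fragment a bisulphite strand (original-top or
#' original-bottom with probability 0.5), draws a per-molecule
#' methylation state for every CpG from the truth table, applies
#' strand-specific in-silico conversion (unmethylated C reads T with
#' probability `conversionRate`; methylated C reads T with probability
#' `conversionFailureRate`; non-CpG cytosines are always unmethylated),
#' adds uniform sequencing errors, and mixes in unmethylated spike-in
#' reads at `spikeInFraction`. Truth alignments are emitted directly: a
#' read contained in an element with exact-duplicate copies receives one
#' alignment record per identical copy (primary plus secondaries, all
#' with `NH` set to the placement count).
#'
#' @param config A [SimConfig-class].
#' @param toy Output of [buildToyGenome()] (genome, annotation, cpgTable).
#' @param alignmentNoise Logical; if `TRUE`, multi-placement reads are
#'   collapsed to a single random placement (keeping `NH` = k), emulating
#'   an aligner that reports one location for ambiguous reads.
#' @return A list with one entry per library (`chip`, `input`), each
#'   holding `records` (truth alignment table as in [readSam()]), `reads`
#'   (named [Biostrings::DNAStringSet], 5'-to-3' as sequenced) and
#'   `origins` (per-read truth: contig, 0-based position, strand,
#'   bisulphite strand, `n_valid_placements`, spike-in flag); plus
#'   `occupiedLoci` (element ids and fold) and `contigLengths`.
#' @examples
#' cfg <- simConfig(genomeLength = 30000L, copiesPerFamily = 8L,
#'                  chipDepth = 500L, inputDepth = 500L, seed = 3L)
#' toy <- buildToyGenome(cfg)
#' sim <- simulateReads(cfg, toy)
#' sim$chip$origins[1:3, ]
#' @export
simulateReads <- function(config, toy, alignmentNoise = FALSE) {
  validObject(config)
  set.seed(config@seed + 1L)
  annotation <- toy$annotation
  wid <- setNames(Biostrings::width(toy$genome), names(toy$genome))
  L1 <- wid[["chrT"]]
  L2 <- wid[["spike"]]
  contigLengths <- c(chrT = L1, spike = L2)
  gchars <- c(strsplit(as.character(toy$genome[["chrT"]]), "")[[1]],
              strsplit(as.character(toy$genome[["spike"]]), "")[[1]])
  offset <- c(chrT = 0L, spike = L1)

  ## per-strand methylation probability lookup in global coordinates
  methP <- rep(NA_real_, L1 + L2)
  methM <- rep(NA_real_, L1 + L2)
  ct <- toy$cpgTable
  gpos <- ct$pos + offset[ct$contig] + 1L
  methP[gpos[ct$strand == "+"]] <- ct$meth_prob[ct$strand == "+"]
  methM[gpos[ct$strand == "-"]] <- ct$meth_prob[ct$strand == "-"]

  ## occupancy truth, shared by both libraries
  occIdx <- sample(seq_along(annotation),
                   min(config@nOccupiedLoci, length(annotation)))
  occupiedLoci <- data.frame(
    element_id = mcols(annotation)$element_id[occIdx],
    fold = config@occupancyFold)
  wChip <- rep(1, L1)
  for (i in occIdx)
    wChip[start(annotation)[i]:end(annotation)[i]] <- config@occupancyFold

  out <- list()
  for (lib in c("chip", "input")) {
    depth <- if (lib == "chip") config@chipDepth else config@inputDepth
    if (depth == 0L) {
      warning("requested depth 0 for ", lib, " library; emitting no reads")
      out[[lib]] <- list(
        records = readSamEmpty(contigLengths),
        reads = Biostrings::DNAStringSet(),
        origins = data.frame(read_id = character(0)))
      next
    }
    w <- if (lib == "chip") wChip else NULL
    out[[lib]] <- simulateLibrary(config, lib, depth, w, gchars, offset,
                                  contigLengths, methP, methM, annotation,
                                  alignmentNoise)
  }
  out$occupiedLoci <- occupiedLoci
  out$contigLengths <- contigLengths
  out
}

readSamEmpty <- function(contigLengths) {
  rec <- data.frame(read_id = character(0), flag = integer(0),
                    contig = character(0), start = numeric(0),
                    strand = character(0), bs_strand = character(0),
                    seq = character(0), n_alignments = integer(0),
                    secondary = logical(0))
  attr(rec, "contigLengths") <- contigLengths
  rec
}

simulateLibrary <- function(config, lib, depth, wChip, gchars, offset,
                            contigLengths, methP, methM, annotation,
                            alignmentNoise) {
  RL <- config@readLength
  L1 <- contigLengths[["chrT"]]
  isSpike <- runif(depth) < config@spikeInFraction
  contig <- ifelse(isSpike, "spike", "chrT")
  clen <- contigLengths[contig]
  center <- integer(depth)
  nG <- sum(!isSpike)
  center[!isSpike] <- sample.int(L1, nG, replace = TRUE, prob = wChip) - 1L
  center[isSpike] <- sample.int(contigLengths[["spike"]], depth - nG,
                                replace = TRUE) - 1L
  flen <- pmax(RL, roundHalfUp(rnorm(depth, config@fragmentLenMean,
                                     config@fragmentLenSd)))
  flen <- pmin(flen, clen)
  fstart <- pmin(pmax(center - flen %/% 2L, 0L), clen - flen)
  bs <- ifelse(runif(depth) < 0.5, "OT", "OB")
  ws <- ifelse(bs == "OT", fstart, fstart + flen - RL)  # read window start
  gws <- ws + offset[contig]

  ## read windows as an n x RL character matrix in plus orientation
  posMat <- matrix(rep(gws, RL) + rep(0:(RL - 1L), each = depth),
                   nrow = depth)
  m <- matrix(gchars[posMat + 1L], nrow = depth)

  ## bisulphite conversion, molecule-level Bernoulli per CpG
  otRows <- bs == "OT"
  convertCells <- function(cells, probVec, convertedBase) {
    gp <- posMat[cells] + 1L
    mp <- probVec[gp]
    n <- length(cells)
    methylated <- !is.na(mp) & runif(n) < ifelse(is.na(mp), 0, mp)
    toConv <- ifelse(methylated,
                     runif(n) < config@conversionFailureRate,
                     runif(n) < config@conversionRate)
    m[cells[toConv]] <<- convertedBase
  }
  cellsOT <- which(m == "C" & otRows)
  if (length(cellsOT)) convertCells(cellsOT, methP, "T")
  cellsOB <- which(m == "G" & !otRows)
  if (length(cellsOB)) convertCells(cellsOB, methM, "A")

  ## sequencing errors after conversion
  err <- which(runif(length(m)) < config@sequencingErrorRate)
  if (length(err)) {
    shift <- sample.int(3L, length(err), replace = TRUE)
    m[err] <- BASES[(match(m[err], BASES) - 1L + shift) %% 4L + 1L]
  }

  plusSeq <- matrixToStrings(m)
  readSeq <- plusSeq
  readSeq[!otRows] <- revCompChar(plusSeq[!otRows])
  readId <- sprintf("%s_%06d", lib, seq_len(depth))

  ## multi-placement truth over exact-duplicate element copies
  k <- rep(1L, depth)
  secondary <- NULL
  rgr <- GRanges(contig, IRanges(ws + 1L, width = RL))
  hit <- findOverlaps(rgr, annotation, type = "within", select = "first")
  multi <- which(!is.na(hit) & mcols(annotation)$dup_size[hit] > 1L)
  if (length(multi)) {
    elem <- hit[multi]
    k[multi] <- mcols(annotation)$dup_size[elem]
    grp <- mcols(annotation)$dup_group[elem]
    sisters <- lapply(seq_along(multi), function(j) {
      members <- which(mcols(annotation)$dup_group == grp[j])
      members[members != elem[j]]
    })
    offsetInElem <- ws[multi] - (start(annotation)[elem] - 1L)
    reps <- lengths(sisters)
    if (sum(reps)) {
      sis <- unlist(sisters)
      i0 <- rep(multi, reps)
      secondary <- data.frame(
        read_id = readId[i0],
        contig = "chrT",
        start = (start(annotation)[sis] - 1L) + rep(offsetInElem, reps),
        strand = ifelse(bs[i0] == "OT", "+", "-"),
        bs_strand = bs[i0],
        seq = plusSeq[i0],
        n_alignments = k[i0],
        secondary = TRUE, stringsAsFactors = FALSE)
    }
  }

  primary <- data.frame(
    read_id = readId, contig = contig, start = ws,
    strand = ifelse(bs == "OT", "+", "-"), bs_strand = bs,
    seq = plusSeq, n_alignments = k, secondary = FALSE,
    stringsAsFactors = FALSE)
  if (alignmentNoise && length(multi)) {
    ## keep one random placement per multi-read, flag records k placements
    for (j in seq_along(multi)) {
      i <- multi[j]
      cand <- c(primary$start[i], secondary$start[secondary$read_id == readId[i]])
      primary$start[i] <- cand[sample.int(length(cand), 1L)]
    }
    secondary <- NULL
  }
  records <- rbind(primary, secondary)
  records <- records[order(match(records$read_id, readId), records$secondary), ]
  rownames(records) <- NULL
  records$flag <- (records$strand == "-") * 16L + records$secondary * 256L
  attr(records, "contigLengths") <- contigLengths

  origins <- data.frame(read_id = readId, contig = contig, start = ws,
                        strand = ifelse(bs == "OT", "+", "-"),
                        bs_strand = bs, n_valid_placements = k,
                        spike_in = isSpike, stringsAsFactors = FALSE)
  list(records = records,
       reads = setNames(Biostrings::DNAStringSet(readSeq), readId),
       origins = origins)
}

#' Run the full generator and write its outputs
#'
#' Convenience wrapper: [buildToyGenome()] then [simulateReads()], with
#' all outputs written to `outdir` (genome FASTA, BED6+2 annotation,
#' FASTQ and truth SAM per library, consensus FASTA, and tab-separated
#' truth tables).
#'
#' @param config A [SimConfig-class].
#' @param outdir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param alignmentNoise Passed to [simulateReads()].
#' @return Invisibly, a list with `toy` ([buildToyGenome()] output) and
#'   `sim` ([simulateReads()] output).
#' @export
simulateExperiment <- function(config, outdir = NULL,
                               alignmentNoise = FALSE) {
  toy <- buildToyGenome(config)
  sim <- simulateReads(config, toy, alignmentNoise = alignmentNoise)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(toy$genome, file.path(outdir, "genome.fa"))
    Biostrings::writeXStringSet(toy$consensi,
                                file.path(outdir, "consensus.fa"))
    writeBedAnnotation(toy$annotation, file.path(outdir, "annotation.bed"))
    write.table(toy$cpgTable, file.path(outdir, "cpg_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sim$occupiedLoci, file.path(outdir, "occupied_loci.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (lib in c("chip", "input")) {
      writeSam(sim[[lib]]$records, sim$contigLengths,
               file.path(outdir, paste0(lib, ".sam")))
      if (length(sim[[lib]]$reads))
        writeFastq(sim[[lib]]$reads, file.path(outdir, paste0(lib, ".fastq")))
      write.table(sim[[lib]]$origins,
                  file.path(outdir, paste0(lib, "_read_origins.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(list(toy = toy, sim = sim))
}
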