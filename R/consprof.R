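## Consensus meta-profiles: select repeat-intersecting reads, realign
## them to family consensus sequences in collapsed bisulphite space, and
## accumulate per-base fraction-methylated profiles on consensus
## coordinates.

#' Build a bisulphite consensus index
#'
#' Concatenates the family consensus sequences with an N spacer and
#' precomputes the two collapsed three-letter forms used for bisulphite
#' matching: C-to-T (original-top strand) and G-to-A (original-bottom
#' strand). The concatenated layout is an internal detail; all reported
#' coordinates are per-family.
#'
#' @param consensi Named [Biostrings::DNAStringSet] (or named character
#'   vector) of family consensus sequences; see [readConsensusFasta()].
#' @param spacer Number of N bases between concatenated consensi.
#' @return A [ConsensusIndex-class] object.
#' @export
consensusIndex <- function(consensi, spacer = 100L) {
  if (!methods::is(consensi, "DNAStringSet"))
    consensi <- Biostrings::DNAStringSet(consensi)
  seqs <- as.character(consensi)
  pad <- strrep("N", spacer)
  cat0 <- paste(seqs, collapse = pad)
  offsets <- cumsum(c(0L, (nchar(seqs) + spacer)[-length(seqs)]))
  new("ConsensusIndex", consensi = consensi, spacer = as.integer(spacer),
      catOT = chartr("C", "T", cat0), catOB = chartr("G", "A", cat0),
      offsets = setNames(as.integer(offsets), names(consensi)))
}

#' Select reads intersecting annotated repeat elements
#'
#' A read is kept when any of its placements overlaps an element of one
#' of the filtered classes by at least 1 bp; each read is returned once,
#' as its original 5'-to-3' sequence (minus-strand placements are
#' reverse-complemented back).
#'
#' @param records Alignment table ([readSam()]/[parseAlignments()]).
#' @param annotation Element [GenomicRanges::GRanges] with a `class`
#'   metadata column, on the same reference.
#' @param classes Character vector of classes to keep (default `"SINE"`).
#' @return A named [Biostrings::DNAStringSet] of unique reads.
#' @export
selectRepeatReads <- function(records, annotation, classes = "SINE") {
  keep <- annotation[mcols(annotation)$class %in% classes]
  if (!length(keep) || !nrow(records))
    return(Biostrings::DNAStringSet())
  gr <- GRanges(records$contig,
                IRanges(records$start + 1L, width = nchar(records$seq)))
  hit <- countOverlaps(gr, keep, ignore.strand = TRUE) > 0
  sel <- records[hit, , drop = FALSE]
  sel <- sel[!duplicated(sel$read_id), , drop = FALSE]
  if (!nrow(sel)) return(Biostrings::DNAStringSet())
  seq5to3 <- ifelse(sel$strand == "-", revCompChar(sel$seq), sel$seq)
  setNames(Biostrings::DNAStringSet(seq5to3), sel$read_id)
}

#' Realign reads to family consensi in collapsed bisulphite space
#'
#' Performs an ungapped scan of each read against every family consensus
#' in the matching collapsed space: the read with C collapsed to T
#' against the C-to-T index (original-top orientation), and the reverse
#' complement of the read with G collapsed to A against the G-to-A index
#' (original-bottom orientation). A placement is valid when its
#' collapsed-space mismatch count is at most
#' `maxMismatchFrac * read length`; all placements within 1 mismatch of
#' the best are reported, up to `maxAlignments` (default 14, the
#' all-alignments consensus realignment cap), with weight 1/k over the
#' reported placements. Reads with more than `maxAlignments` near-best
#' placements are dropped and counted; reads longer than every consensus
#' are skipped and counted.
#'
#' @param reads Named [Biostrings::DNAStringSet] (e.g. from
#'   [selectRepeatReads()]).
#' @param index A [ConsensusIndex-class].
#' @param maxAlignments Cap on reported near-best placements.
#' @param maxMismatchFrac Mismatch budget as a fraction of read length
#'   (default 0.2).
#' @return A `data.frame` with one row per reported placement:
#'   `read_id`, `family`, `offset` (0-based within the family
#'   consensus), `mode` (`OT`/`OB`), `mismatches`, `weight`. Attributes
#'   `unaligned`, `dropped` (over-cap) and `skipped` (too long) count
#'   the discarded reads.
#' @export
bisulfiteRealign <- function(reads, index, maxAlignments = 14L,
                             maxMismatchFrac = 0.2) {
  famLen <- setNames(nchar(as.character(index@consensi)),
                     names(index@consensi))
  maxFamLen <- max(famLen)
  subjOT <- Biostrings::DNAString(index@catOT)
  subjOB <- Biostrings::DNAString(index@catOB)
  empty <- data.frame(read_id = character(0), family = character(0),
                      offset = integer(0), mode = character(0),
                      mismatches = integer(0), weight = numeric(0))
  counters <- c(unaligned = 0L, dropped = 0L, skipped = 0L)
  if (!length(reads)) {
    attr(empty, "unaligned") <- 0L; attr(empty, "dropped") <- 0L
    attr(empty, "skipped") <- 0L
    return(empty)
  }
  ## collapse once per distinct sequence
  seqChar <- as.character(reads)
  uniq <- unique(seqChar)
  hitList <- vector("list", length(uniq))
  names(hitList) <- uniq
  for (s in uniq) {
    len <- nchar(s)
    if (len > maxFamLen) { hitList[[s]] <- "skipped"; next }
    mm <- floor(maxMismatchFrac * len)
    patOT <- Biostrings::DNAString(chartr("C", "T", s))
    patOB <- Biostrings::DNAString(
      chartr("G", "A", as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))))
    hits <- rbind(scanIndex(patOT, subjOT, mm, "OT", index, famLen),
                  scanIndex(patOB, subjOB, mm, "OB", index, famLen))
    if (is.null(hits) || !nrow(hits)) { hitList[[s]] <- "unaligned"; next }
    best <- min(hits$mismatches)
    hits <- hits[hits$mismatches <= best + 1L, , drop = FALSE]
    if (nrow(hits) > maxAlignments) { hitList[[s]] <- "dropped"; next }
    hits$weight <- 1 / nrow(hits)
    hitList[[s]] <- hits
  }
  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    h <- hitList[[seqChar[i]]]
    if (is.character(h)) {
      counters[h] <- counters[h] + 1L
      next
    }
    h$read_id <- names(reads)[i]
    out[[i]] <- h
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  res <- res[, c("read_id", "family", "offset", "mode", "mismatches",
                 "weight")]
  attr(res, "unaligned") <- counters[["unaligned"]]
  attr(res, "dropped") <- counters[["dropped"]]
  attr(res, "skipped") <- counters[["skipped"]]
  res
}

# Ungapped scan of one collapsed pattern against one collapsed index;
# placements spanning the N spacer (i.e. not fully inside one family)
# are discarded. Returns family-relative offsets and mismatch counts.
scanIndex <- function(pattern, subject, mm, mode, index, famLen) {
  hits <- Biostrings::matchPattern(pattern, subject, max.mismatch = mm,
                                   with.indels = FALSE)
  if (!length(hits)) return(NULL)
  st <- Biostrings::start(hits) - 1L       # 0-based in concatenated index
  en <- st + length(pattern)
  fam <- names(index@offsets)[findInterval(st, index@offsets)]
  off <- st - index@offsets[fam]
  inside <- off >= 0L & en - index@offsets[fam] <= famLen[fam]
  if (!any(inside)) return(NULL)
  nm <- vapply(which(inside), function(j)
    Biostrings::neditStartingAt(pattern, subject,
                                starting.at = st[j] + 1L,
                                with.indels = FALSE), integer(1))
  data.frame(family = fam[inside], offset = as.integer(off[inside]),
             mode = mode, mismatches = nm, stringsAsFactors = FALSE)
}

#' Build per-base methylation profiles on consensus coordinates
#'
#' For every reported consensus placement, classifies the original
#' (uncollapsed) read bases at consensus cytosines exactly as
#' [callCytosines()] does - OT placements at consensus C positions
#' (read C = methylated, T = unmethylated), OB placements at consensus G
#' positions (read G = methylated, A = unmethylated) - and accumulates
#' the placement weights into per-position methylated/unmethylated
#' arrays for each family.
#'
#' @param alignments Placement table from [bisulfiteRealign()].
#' @param index The [ConsensusIndex-class] used for realignment.
#' @param reads The named [Biostrings::DNAStringSet] that was realigned
#'   (source of original read bases).
#' @return A named list of [ConsensusProfile-class] objects, one per
#'   family with at least one placement.
#' @export
profileFromAlignments <- function(alignments, index, reads) {
  profiles <- list()
  if (!nrow(alignments)) return(profiles)
  seqChar <- as.character(reads)
  for (famName in unique(alignments$family)) {
    cons <- strsplit(as.character(index@consensi[[famName]]), "")[[1]]
    meth <- numeric(length(cons)); unmeth <- numeric(length(cons))
    al <- alignments[alignments$family == famName, , drop = FALSE]
    for (r in seq_len(nrow(al))) {
      s <- seqChar[[al$read_id[r]]]
      rc <- if (al$mode[r] == "OB")
        strsplit(revCompChar(s), "")[[1]] else strsplit(s, "")[[1]]
      span <- al$offset[r] + seq_along(rc)      # 1-based consensus pos
      target <- if (al$mode[r] == "OT") "C" else "G"
      unconv <- if (al$mode[r] == "OT") "C" else "G"
      conv <- if (al$mode[r] == "OT") "T" else "A"
      at <- which(cons[span] == target)
      if (!length(at)) next
      rb <- rc[at]
      cp <- span[at]
      w <- al$weight[r]
      mHit <- cp[rb == unconv]
      uHit <- cp[rb == conv]
      if (length(mHit)) {
        tm <- tabulate(mHit, nbins = length(cons))
        meth <- meth + w * tm
      }
      if (length(uHit)) {
        tu <- tabulate(uHit, nbins = length(cons))
        unmeth <- unmeth + w * tu
      }
    }
    profiles[[famName]] <- new("ConsensusProfile", family = famName,
                               consensus = paste(cons, collapse = ""),
                               meth = meth, unmeth = unmeth,
                               blocks = list())
  }
  profiles
}

#' Realign reads and profile them in one step
#'
#' Convenience wrapper chaining [bisulfiteRealign()] and
#' [profileFromAlignments()].
#'
#' @inheritParams bisulfiteRealign
#' @return A named list of [ConsensusProfile-class] objects.
#' @export
profileReads <- function(reads, index, maxAlignments = 14L,
                         maxMismatchFrac = 0.2) {
  al <- bisulfiteRealign(reads, index, maxAlignments = maxAlignments,
                         maxMismatchFrac = maxMismatchFrac)
  profileFromAlignments(al, index, reads)
}

# Write profiles as a per-position TSV and a wig-style fraction track.
writeProfiles <- function(profiles, prefix) {
  rows <- lapply(profiles, function(p) {
    fr <- profileFraction(p)
    data.frame(family = p@family, pos = seq_along(p@meth) - 1L,
               base = strsplit(p@consensus, "")[[1]],
               meth = p@meth, unmeth = p@unmeth,
               fraction = ifelse(is.na(fr), NA, round(fr, 4)))
  })
  df <- do.call(rbind, rows)
  write.table(df, paste0(prefix, ".profile.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  con <- file(paste0(prefix, ".profile.wig"), "wt")
  on.exit(close(con))
  for (p in profiles) {
    writeLines(sprintf("track type=wiggle_0 name=\"%s methylation\"",
                       p@family), con)
    writeLines(sprintf("fixedStep chrom=%s start=1 step=1", p@family), con)
    fr <- profileFraction(p)
    writeLines(ifelse(is.na(fr), "0", format(round(fr, 4))), con)
  }
  invisible(prefix)
}
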