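## File I/O: FASTA/FASTQ via Biostrings, BED via rtracklayer, SAM as a
## light-weight text reader/writer (text SAM with NH/XB tags; coordinates
## converted 1-based <-> 0-based exactly once at this boundary).

#' Read a text SAM file into an alignment table
#'
#' Parses a plain-text SAM file into the flat alignment-record table used
#' by the package. One row per alignment record; multi-mapping reads
#' occupy several rows (secondary alignments have SAM flag bit 0x100).
#' Unmapped records (flag bit 0x4) are skipped. The `NH` tag (number of
#' reported alignments) and `XB` tag (bisulphite strand, `OT`/`OB`) are
#' extracted when present; when `XB` is absent the bisulphite strand is
#' inferred from the alignment strand (plus = OT, minus = OB, the
#' directional-library convention).
#'
#' @param path Path to a SAM file with header lines.
#' @return A `data.frame` with columns `read_id`, `flag`, `contig`,
#'   `start` (0-based), `strand` (`+`/`-`), `bs_strand` (`OT`/`OB`),
#'   `seq` (bases as stored, i.e. plus-strand orientation), `n_alignments`
#'   and `secondary`. Contig lengths from `@SQ` lines are attached as
#'   attribute `contigLengths`; the number of skipped unmapped records as
#'   attribute `unmapped`.
#' @seealso [parseAlignments()] for multi-mapper weighting, [writeSam()]
#' @export
readSam <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "@"))
    stop("SAM parse error at line 1: missing header (expected '@' line) in ",
         path)
  isHeader <- startsWith(lines, "@")
  headerLines <- lines[isHeader]
  sq <- headerLines[startsWith(headerLines, "@SQ")]
  contigLengths <- numeric(0)
  if (length(sq)) {
    nm <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.numeric(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    contigLengths <- setNames(ln, nm)
  }
  body <- which(!isHeader)
  if (!length(body)) {
    rec <- data.frame(read_id = character(0), flag = integer(0),
                      contig = character(0), start = numeric(0),
                      strand = character(0), bs_strand = character(0),
                      seq = character(0), n_alignments = integer(0),
                      secondary = logical(0))
    attr(rec, "contigLengths") <- contigLengths
    attr(rec, "unmapped") <- 0L
    return(rec)
  }
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("SAM parse error at line ", body[which(nf < 11L)[1]],
         ": fewer than 11 fields")
  flag <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  pos <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  bad <- which(is.na(flag) | is.na(pos))
  if (length(bad))
    stop("SAM parse error at line ", body[bad[1]],
         ": non-numeric FLAG or POS")
  tagOf <- function(f, tag) {
    if (length(f) <= 11L) return(NA_character_)
    extra <- f[12:length(f)]
    hit <- extra[startsWith(extra, tag)]
    if (length(hit)) sub("^[A-Za-z0-9]+:[AifZ]:", "", hit[1]) else NA_character_
  }
  nh <- vapply(fields, tagOf, "", tag = "NH:")
  xb <- vapply(fields, tagOf, "", tag = "XB:")
  rec <- data.frame(
    read_id = vapply(fields, `[[`, "", 1L),
    flag = flag,
    contig = vapply(fields, `[[`, "", 3L),
    start = pos - 1,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    seq = vapply(fields, `[[`, "", 10L),
    n_alignments = ifelse(is.na(nh), 1L, suppressWarnings(as.integer(nh))),
    secondary = bitwAnd(flag, 256L) > 0L,
    stringsAsFactors = FALSE)
  rec$bs_strand <- ifelse(!is.na(xb), xb,
                          ifelse(rec$strand == "+", "OT", "OB"))
  unmapped <- bitwAnd(rec$flag, 4L) > 0L
  out <- rec[!unmapped, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "contigLengths") <- contigLengths
  attr(out, "unmapped") <- sum(unmapped)
  out
}

#' Write an alignment table as text SAM
#'
#' Inverse of [readSam()] for the fields the package models. 0-based
#' starts are converted to 1-based POS; `NH` and `XB` tags are emitted.
#'
#' @param records Alignment `data.frame` as produced by [readSam()] or the
#'   simulator.
#' @param contigLengths Named numeric of contig lengths for `@SQ` lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSam <- function(records, contigLengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigLengths),
                   as.integer(contigLengths)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(records)) {
    flag <- if ("flag" %in% names(records)) records$flag else
      (records$strand == "-") * 16L + records$secondary * 256L
    lines <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNH:i:%d\tXB:Z:%s",
                     records$read_id, as.integer(flag), records$contig,
                     as.integer(records$start) + 1L,
                     nchar(records$seq), records$seq,
                     strrep("I", nchar(records$seq)),
                     as.integer(records$n_alignments), records$bs_strand)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read an element annotation from BED6+2
#'
#' Reads a BED file whose 6 standard columns are followed by `family` and
#' `class` columns, as written by [writeBedAnnotation()] (the annotation
#' format of the synthetic genome and of RepeatMasker-style element
#' lists).
#'
#' @param path Path to a BED6+2 file.
#' @return A [GenomicRanges::GRanges] with metadata columns `element_id`,
#'   `family` and `class`.
#' @export
readBedAnnotation <- function(path) {
  gr <- rtracklayer::import(path, format = "BED",
                            extraCols = c(family = "character",
                                          class = "character"))
  mcols(gr)$element_id <- mcols(gr)$name
  mcols(gr)$name <- NULL
  mcols(gr)$score <- NULL
  gr
}

#' Write an element annotation as BED6+2
#'
#' @param annotation A [GenomicRanges::GRanges] with `element_id`,
#'   `family` and `class` metadata columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBedAnnotation <- function(annotation, path) {
  df <- data.frame(
    chrom = as.character(seqnames(annotation)),
    start = start(annotation) - 1L,
    end = end(annotation),
    name = mcols(annotation)$element_id,
    score = 0L,
    strand = as.character(strand(annotation)),
    family = mcols(annotation)$family,
    class = mcols(annotation)$class)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a bedGraph track
#'
#' Emits a sorted, non-overlapping bedGraph (0-based half-open intervals).
#'
#' @param contig,start,end,value Parallel vectors describing the track;
#'   `start`/`end` are 0-based half-open.
#' @param path Output path.
#' @param name Track name for the header line.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(contig, start, end, value, path, name = "track") {
  o <- order(contig, start)
  df <- data.frame(contig = contig[o], start = as.integer(start[o]),
                   end = as.integer(end[o]), value = value[o])
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write reads as FASTQ
#'
#' @param reads A named [Biostrings::DNAStringSet] (names become read ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Read FASTQ reads
#'
#' @param path Path to an (uncompressed) FASTQ file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readFastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Read consensus sequences from FASTA
#'
#' Repbase-style headers are reduced to their first whitespace-delimited
#' token, which becomes the family name.
#'
#' @param path Path to a FASTA file of family consensus sequences.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readConsensusFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- vapply(strsplit(names(x), "\\s+"), `[[`, "", 1L)
  x
}

# Write cytosine calls as a tab-separated table plus the two bedGraph
# tracks (fraction and coverage) customary for methylation data.
writeCalls <- function(calls, prefix) {
  df <- data.frame(contig = as.character(seqnames(calls)),
                   pos = start(calls) - 1L,
                   strand = as.character(strand(calls)),
                   context = mcols(calls)$context,
                   meth = mcols(calls)$meth,
                   unmeth = mcols(calls)$unmeth)
  write.table(df, paste0(prefix, ".calls.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cov <- df$meth + df$unmeth
  ok <- cov > 0
  writeBedGraph(df$contig[ok], df$pos[ok], df$pos[ok] + 1L,
                round(df$meth[ok] / cov[ok], 4),
                paste0(prefix, ".fraction.bedGraph"), name = "fraction")
  writeBedGraph(df$contig[ok], df$pos[ok], df$pos[ok] + 1L,
                round(cov[ok], 3),
                paste0(prefix, ".coverage.bedGraph"), name = "coverage")
  invisible(prefix)
}
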