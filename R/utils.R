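#' @import methods
#' @importFrom stats p.adjust pbinom dhyper pnorm rnorm runif setNames
#'   kruskal.test pchisq
#' @importFrom utils write.table read.table packageVersion head tail
#' @importFrom data.table data.table setorderv setnames set .N .SD
NULL

.datatable.aware <- TRUE

# Phred transform used throughout: -10 log10, capped so that p = 0 (or an
# empirical FDR of 0) maps to the cap rather than Inf.
phredScale <- function(p, cap = 100) {
  out <- -10 * log10(p)
  out[!is.finite(out)] <- cap
  pmin(pmax(out, 0), cap)
}

# Round half-up (round() rounds half-to-even, which would make the exact
# tests depend on the parity of weighted counts).
roundHalfUp <- function(x) floor(x + 0.5)

#' Test two intervals for overlap (0-based half-open)
#'
#' Interval arithmetic helper used by the interval-based stages. Intervals
#' are 0-based half-open, so `[0, 10)` and `[10, 20)` are adjacent, not
#' overlapping.
#'
#' @param start1,end1,start2,end2 Numeric vectors of interval bounds,
#'   0-based half-open.
#' @return Logical vector, `TRUE` where the intervals share at least 1 bp.
#' @examples
#' intervalsOverlap(0, 10, 9, 20)   # TRUE, share base 9
#' intervalsOverlap(0, 10, 10, 20)  # FALSE, adjacent
#' @export
intervalsOverlap <- function(start1, end1, start2, end2) {
  pmax(start1, start2) < pmin(end1, end2)
}

# Weighted count of points falling in [start, end) per query interval.
# `pos` need not be sorted; all vectors are numeric. Returns a numeric
# vector parallel to `starts`.
weightedRangeSums <- function(pos, weights, starts, ends) {
  o <- order(pos)
  pos <- pos[o]
  cw <- cumsum(weights[o])
  hi <- findInterval(ends - 0.5, pos)    # points with pos <= end - 1
  lo <- findInterval(starts - 0.5, pos)  # points with pos <= start - 1
  hiSum <- ifelse(hi > 0, cw[pmax(hi, 1)], 0)
  loSum <- ifelse(lo > 0, cw[pmax(lo, 1)], 0)
  hiSum - loSum
}

# Reverse-complement plain character vectors of DNA (used where building a
# DNAStringSet would dominate runtime for many short strings).
revCompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split a set of equal-length strings into an n x L character matrix.
stringsToMatrix <- function(x, len) {
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = len, byrow = TRUE)
}

# Collapse rows of a character matrix back to strings.
matrixToStrings <- function(m) {
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
}
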