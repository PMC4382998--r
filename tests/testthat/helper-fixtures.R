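suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# Small simulation used by several module tests.
tinyConfig <- function(...) {
  defaults <- list(genomeLength = 30000L, copiesPerFamily = 8L,
                   nTrnaLoci = 4L, nOccupiedLoci = 6L, occupancyFold = 8,
                   chipDepth = 1500L, inputDepth = 1500L, seed = 101L)
  do.call(simConfig, utils::modifyList(defaults, list(...)))
}

# Construct a CytosineCalls object directly from parallel vectors.
makeCalls <- function(contig, pos, strand, context, meth, unmeth) {
  gr <- GRanges(contig, IRanges(pos + 1L, width = 1L), strand = strand,
                context = context, meth = meth, unmeth = unmeth)
  new("CytosineCalls", gr)
}

# Write SAM text for hand-built records; fields beyond the 11 mandatory
# ones are tag strings.
samText <- function(path, contigLengths, lines) {
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigLengths),
                   as.integer(contigLengths)))
  writeLines(c(hdr, lines), path)
  path
}

samLine <- function(qname, flag, rname, pos1, seq, ...) {
  paste(c(qname, flag, rname, pos1, "255", paste0(nchar(seq), "M"),
          "*", "0", "0", seq, strrep("I", nchar(seq)), ...),
        collapse = "\t")
}

# Build an alignment-record data.frame in the package's internal layout.
recDf <- function(read_id, contig, start, strand, bs_strand, seq,
                  n_alignments = 1L, weight = 1, secondary = FALSE,
                  contigLengths = NULL) {
  df <- data.frame(read_id = read_id, contig = contig, start = start,
                   strand = strand, bs_strand = bs_strand, seq = seq,
                   n_alignments = n_alignments, secondary = secondary,
                   weight = weight, stringsAsFactors = FALSE)
  attr(df, "contigLengths") <- contigLengths
  df
}

# Independent two-sided Fisher p by full enumeration over tables with
# fixed margins, probabilities from log-binomial coefficients (the
# oracle route; never calls the package implementation).
fisherEnumOracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 + m2 == 0) return(1)
  xs <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, xs) + lchoose(m2, k - xs) - lchoose(m1 + m2, k)
  p <- exp(logp)
  pObs <- exp(lchoose(m1, a) + lchoose(m2, c) - lchoose(m1 + m2, k))
  min(1, sum(p[p <= pObs * (1 + 1e-7)]))
}

# Independent tie-corrected Kruskal-Wallis H from first principles.
kwOracleH <- function(values, labels) {
  N <- length(values)
  r <- rank(values)
  Rbar <- tapply(r, labels, mean)
  n <- tapply(r, labels, length)
  H <- 12 / (N * (N + 1)) * sum(n * (Rbar - (N + 1) / 2)^2)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Sampled permutation p-value for the KW statistic (shared by the oracle
# tests); built on kwOracleH's formula, not on the package. Permuting the
# rank vector and regrouping by position is equivalent to permuting
# labels; group rank sums are accumulated column-wise for speed.
kwPermP <- function(values, labels, B) {
  N <- length(values)
  r <- rank(values)
  labs <- unique(labels)
  n <- as.numeric(table(factor(labels, levels = labs)))
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  Hobs <- kwOracleH(values, labels)
  permMat <- vapply(seq_len(B), function(b) r[sample.int(N)], numeric(N))
  cs <- cumsum(c(0, n))
  sums <- vapply(seq_along(labs), function(g)
    colSums(permMat[(cs[g] + 1):cs[g + 1], , drop = FALSE]), numeric(B))
  Rbar <- sweep(sums, 2, n, "/")
  Hperm <- (12 / (N * (N + 1)) *
            as.numeric((Rbar - (N + 1) / 2)^2 %*% n)) / corr
  mean(Hperm >= Hobs - 1e-9)
}
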