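test_that("multi-mapper weighting follows the 1/k rule and the cap", {
  tmp <- tempfile(fileext = ".sam")
  lines <- c(
    samLine("u1", 0, "c1", 1, "ACGT"),
    samLine("m4", 0, "c1", 11, "ACGT", "NH:i:4"),
    samLine("m4", 256, "c1", 21, "ACGT", "NH:i:4"),
    samLine("m4", 256, "c1", 31, "ACGT", "NH:i:4"),
    samLine("m4", 256, "c1", 41, "ACGT", "NH:i:4"),
    samLine("m9", 0, "c1", 51, "ACGT", "NH:i:9"))
  samText(tmp, c(c1 = 100L), lines)
  aln <- parseAlignments(tmp, maxAlignments = 7L)
  expect_identical(attr(aln, "dropped"), 1L)
  expect_false("m9" %in% aln$read_id)
  expect_equal(aln$weight[aln$read_id == "u1"], 1)
  expect_equal(aln$weight[aln$read_id == "m4"], rep(0.25, 4))
  ## weight conservation: kept reads sum to 1
  expect_equal(as.numeric(tapply(aln$weight, aln$read_id, sum)), c(1, 1))
  ## unit-weight scheme for sensitivity analysis
  alnU <- parseAlignments(tmp, maxAlignments = 7L, weightScheme = "unit")
  expect_equal(alnU$weight[alnU$read_id == "m4"], rep(1, 4))
})

test_that("SAM parsing reports malformed input with line numbers", {
  tmp <- tempfile(fileext = ".sam")
  writeLines(c("r1\t0\tc1\t1\t255\t4M\t*\t0\t0\tACGT\tIIII"), tmp)
  expect_error(readSam(tmp), "line 1.*header")
  samText(tmp, c(c1 = 100L), "r1\t0\tc1")
  expect_error(readSam(tmp), "line 3")
  samText(tmp, c(c1 = 100L), samLine("r1", 0, "c1", "x", "ACGT"))
  expect_error(readSam(tmp), "line 3")
  ## unmapped records skipped, not parsed
  samText(tmp, c(c1 = 100L), c(samLine("r1", 4, "c1", 1, "ACGT"),
                               samLine("r2", 0, "c1", 1, "ACGT")))
  rec <- readSam(tmp)
  expect_identical(nrow(rec), 1L)
  expect_identical(attr(rec, "unmapped"), 1L)
})

test_that("cytosine calling matches hand-counted OT examples", {
  ##            0123456789
  genome <- DNAStringSet(c(c1 = "AACGTTACGA"))
  ## OT read matching the reference over both CpGs (C at 2 and 7)
  aln <- recDf("r1", "c1", 0L, "+", "OT", "AACGTTACGA")
  calls <- callCytosines(aln, genome)
  df <- as.data.frame(calls)
  cpg <- df[df$context == "CpG", ]
  expect_identical(cpg$start - 1L, c(2L, 7L))   # 0-based positions
  expect_equal(cpg$meth, c(1, 1))
  expect_equal(cpg$unmeth, c(0, 0))
  ## converted read: C->T at both CpGs
  calls2 <- callCytosines(recDf("r2", "c1", 0L, "+", "OT", "AATGTTATGA"),
                          genome)
  df2 <- as.data.frame(calls2)
  expect_equal(df2$unmeth[df2$context == "CpG"], c(1, 1))
  ## sequencing-error base (G at a C position) is ignored entirely
  calls3 <- callCytosines(recDf("r3", "c1", 0L, "+", "OT", "AAGGTTAGGA"),
                          genome)
  expect_identical(sum(as.data.frame(calls3)$start - 1L %in% c(2L, 7L)), 0L)
})

test_that("OB calling uses reference minus-strand cytosines", {
  ## plus strand: A C G T A; minus-strand C sits at the G (0-based pos 2)
  genome <- DNAStringSet(c(c1 = "ACGTA"))
  ## OB read stored in plus orientation, matching reference: G retained
  callsM <- callCytosines(recDf("r1", "c1", 0L, "-", "OB", "ACGTA"), genome)
  df <- as.data.frame(callsM)
  expect_identical(df$start - 1L, 2L)
  expect_identical(as.character(df$strand), "-")
  expect_identical(df$context, "CpG")           # minus C followed by G
  expect_equal(df$meth, 1)
  ## converted: G read as A on the plus representation
  callsC <- callCytosines(recDf("r2", "c1", 0L, "-", "OB", "ACATA"), genome)
  expect_equal(as.data.frame(callsC)$unmeth, 1)
})

test_that("weighted fractions reproduce a manual 7:3 count", {
  genome <- DNAStringSet(c(c1 = "AACGTT"))
  seqs <- c(rep("AACGTT", 7), rep("AATGTT", 3))
  aln <- recDf(sprintf("r%02d", 1:10), "c1", 0L, "+", "OT", seqs)
  calls <- callCytosines(aln, genome)
  cpg <- as.data.frame(calls[mcols(calls)$context == "CpG"])
  expect_equal(cpg$meth / (cpg$meth + cpg$unmeth), 0.7)
})

test_that("context assignment distinguishes CpG, CHG and CHH", {
  ##                         0123456789
  genome <- DNAStringSet(c(c1 = "ACGACGGACTTCAT"))
  ## positions: C2? layout: A C G A C G G A C T T C A T
  aln <- recDf("r1", "c1", 0L, "+", "OT", "ACGACGGACTTCAT")
  calls <- callCytosines(aln, genome)
  df <- as.data.frame(calls)
  ctx <- setNames(df$context, df$start - 1L)
  expect_identical(unname(ctx["1"]), "CpG")   # C followed by G
  expect_identical(unname(ctx["4"]), "CpG")
  expect_identical(unname(ctx["8"]), "CHH")   # C,T,T
  expect_identical(unname(ctx["11"]), "CHH")  # C,A,T
})

test_that("records extending past the contig end are skipped with warning", {
  genome <- DNAStringSet(c(c1 = "ACGTACGT"))
  aln <- recDf(c("ok", "over"), "c1", c(0L, 6L), "+", "OT",
               c("ACGT", "ACGT"))
  expect_warning(calls <- callCytosines(aln, genome), "skipped")
  expect_identical(S4Vectors::metadata(calls)$skipped, 1L)
  expect_true(all(as.data.frame(calls)$start - 1L < 6L))
})

test_that("strand symmetry: mirrored input yields mirrored calls", {
  set.seed(11)
  g <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
             collapse = "")
  genome <- DNAStringSet(c(c1 = g))
  gRC <- DNAStringSet(c(c1 = as.character(reverseComplement(DNAString(g)))))
  starts <- c(0L, 10L, 25L, 31L)
  seqs <- vapply(starts, function(s) substr(g, s + 1, s + 20), "")
  aln <- recDf(sprintf("r%d", 1:4), "c1", starts, "+", "OT", seqs)
  ## mirror: same molecules seen from the reverse-complemented genome,
  ## where each OT read becomes an OB read at the mirrored coordinate
  alnM <- recDf(sprintf("r%d", 1:4), "c1", 60L - (starts + 20L), "-", "OB",
                vapply(seqs, function(s)
                  as.character(reverseComplement(DNAString(s))), ""))
  callsF <- as.data.frame(callCytosines(aln, genome))
  callsM <- as.data.frame(callCytosines(alnM, gRC))
  ## map mirrored calls back: pos = L - 1 - pos', strand flips back
  callsF$pos0 <- callsF$start - 1L
  callsM$pos0 <- 60L - callsM$start            # = 59 - (start - 1)
  cols <- c("pos0", "context", "meth", "unmeth")
  o1 <- callsF[order(callsF$pos0), cols]
  o2 <- callsM[order(callsM$pos0), cols]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("symmetric CpG pooling merges strand pairs", {
  genome <- DNAStringSet(c(c1 = "AACGTT"))
  aln <- recDf(c("a", "b", "c"), "c1", 0L, c("+", "+", "-"),
               c("OT", "OT", "OB"), c("AACGTT", "AATGTT", "AACGTT"))
  pooled <- callCytosines(aln, genome, poolCpG = TRUE)
  df <- as.data.frame(pooled)
  cpg <- df[df$context == "CpG", ]
  expect_identical(nrow(cpg), 1L)
  expect_equal(cpg$meth, 2)    # one retained OT + one retained OB
  expect_equal(cpg$unmeth, 1)
})

test_that("conversion estimation matches arithmetic and errors when empty", {
  calls <- makeCalls("spike", c(10L, 20L), "+", c("CHH", "CpG"),
                     meth = c(3, 10), unmeth = c(4987, 5000))
  est <- estimateConversion(calls, "spike")
  expect_equal(est$rate, 9987 / 10000)
  expect_output(print(est), "99.87")
  noSpike <- makeCalls("chrT", 10L, "+", "CpG", 1, 1)
  expect_error(estimateConversion(noSpike, "spike"), "no conversion control")
})

test_that("methylation and conversion rates are recovered from simulation", {
  cfg <- tinyConfig(methProb = c(0.5, 0.5, 0.5), backgroundMethProb = 0.5,
                    trnaMethProb = 0.5, conversionRate = 1,
                    conversionFailureRate = 0, sequencingErrorRate = 0,
                    chipDepth = 4000L, inputDepth = 0L,
                    spikeInFraction = 0.05)
  toy <- buildToyGenome(cfg)
  sim <- suppressWarnings(simulateReads(cfg, toy))
  calls <- callCytosines(parseAlignments(sim$chip$records), toy$genome)
  cpg <- mcols(calls)$context == "CpG" &
    as.character(seqnames(calls)) == "chrT"
  m <- sum(mcols(calls)$meth[cpg]); n <- m + sum(mcols(calls)$unmeth[cpg])
  expect_lt(abs(m / n - 0.5), 3 * sqrt(0.25 / n))
  est <- estimateConversion(calls)
  expect_lt(abs(est$rate - 1), 3 * sqrt(1e-6 + 0 / est$total))
})
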