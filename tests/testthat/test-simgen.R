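test_that("config validation rejects out-of-range parameters", {
  expect_error(simConfig(conversionRate = 1.2), "probabilities")
  expect_error(simConfig(genomeLength = 0L), "positive")
  expect_error(simConfig(occupancyFold = 0.5), "occupancyFold")
  expect_s4_class(tinyConfig(), "SimConfig")
})

test_that("zero divergence makes all copies of a family identical", {
  cfg <- tinyConfig(familyDivergence = 0, nTrnaLoci = 0L)
  toy <- buildToyGenome(cfg)
  ann <- toy$annotation
  gseq <- toy$genome[["chrT"]]
  for (fam in unique(ann$family)) {
    sel <- ann[ann$family == fam]
    seqs <- vapply(seq_along(sel), function(i) {
      s <- as.character(subseq(gseq, start(sel)[i], end(sel)[i]))
      if (as.character(strand(sel))[i] == "-")
        s <- as.character(reverseComplement(DNAString(s)))
      s
    }, "")
    expect_length(unique(seqs), 1L)
  }
})

test_that("zero CpG density leaves no CpG truth rows inside the family", {
  cfg <- tinyConfig(cpgDensity = c(8, 5, 0))
  toy <- buildToyGenome(cfg)
  zeroFam <- toy$annotation[toy$annotation$family == "AluJ-like"]
  cpg <- GRanges(toy$cpgTable$contig,
                 IRanges(toy$cpgTable$pos + 1L, width = 1L))
  expect_identical(sum(countOverlaps(cpg, zeroFam, ignore.strand = TRUE)), 0L)
  ## non-zero families do have CpGs
  otherFam <- toy$annotation[toy$annotation$family == "AluY-like"]
  expect_gt(sum(countOverlaps(cpg, otherFam, ignore.strand = TRUE)), 0L)
})

test_that("annotation row counts follow the configuration", {
  cfg <- tinyConfig(copiesPerFamily = 20L, nFamilies = 3L, nTrnaLoci = 5L,
                    genomeLength = 50000L)
  toy <- buildToyGenome(cfg)
  expect_identical(sum(toy$annotation$class == "SINE"), 60L)
  expect_identical(sum(toy$annotation$class == "tRNA"), 5L)
  ## every element annotated with family, class, strand
  expect_true(all(nchar(toy$annotation$family) > 0))
  expect_true(all(as.character(strand(toy$annotation)) %in% c("+", "-")))
})

test_that("each family contains at least one exact-duplicate pair", {
  toy <- buildToyGenome(tinyConfig())
  ann <- toy$annotation[toy$annotation$class == "SINE"]
  for (fam in unique(ann$family))
    expect_gte(max(ann$dup_size[ann$family == fam]), 2L)
})

test_that("an overfull genome raises a sizing error naming the deficit", {
  expect_error(buildToyGenome(tinyConfig(genomeLength = 5000L)),
               "more bases")
})

test_that("every CpG appears exactly once per strand in the truth table", {
  toy <- buildToyGenome(tinyConfig())
  ct <- toy$cpgTable
  expect_false(any(duplicated(ct[, c("contig", "pos", "strand")])))
  ## independent recount of CpG dinucleotides on the main contig
  hits <- matchPattern("CG", toy$genome[["chrT"]])
  expect_identical(sum(ct$contig == "chrT" & ct$strand == "+"),
                   length(hits))
  expect_identical(sum(ct$contig == "chrT" & ct$strand == "-"),
                   length(hits))
  ## spike-in CpGs are all unmethylated
  expect_true(all(ct$meth_prob[ct$contig == "spike"] == 0))
})

test_that("identical config and seed give identical reads and records", {
  cfg <- tinyConfig(chipDepth = 400L, inputDepth = 400L)
  s1 <- simulateReads(cfg, buildToyGenome(cfg))
  s2 <- simulateReads(cfg, buildToyGenome(cfg))
  expect_identical(as.character(s1$chip$reads), as.character(s2$chip$reads))
  expect_identical(s1$chip$records, s2$chip$records)
  expect_identical(s1$input$origins, s2$input$origins)
})

test_that("read accounting: one primary record and one origin per read", {
  cfg <- tinyConfig(chipDepth = 600L, inputDepth = 300L)
  sim <- simulateReads(cfg, buildToyGenome(cfg))
  for (lib in c("chip", "input")) {
    depth <- if (lib == "chip") 600L else 300L
    expect_identical(sum(!sim[[lib]]$records$secondary), depth)
    expect_identical(nrow(sim[[lib]]$origins), depth)
    expect_false(any(duplicated(sim[[lib]]$origins$read_id)))
    ## multi-placement reads own exactly n_valid_placements records
    tab <- table(sim[[lib]]$records$read_id)
    k <- sim[[lib]]$origins$n_valid_placements
    names(k) <- sim[[lib]]$origins$read_id
    expect_identical(as.integer(tab), as.integer(k[names(tab)]))
  }
})

test_that("zero depth warns and emits empty outputs", {
  cfg <- tinyConfig(chipDepth = 0L, inputDepth = 100L)
  expect_warning(sim <- simulateReads(cfg, buildToyGenome(cfg)),
                 "depth 0")
  expect_identical(nrow(sim$chip$records), 0L)
  expect_identical(length(sim$chip$reads), 0L)
  expect_identical(nrow(sim$input$origins), 100L)
})

test_that("complete conversion with no methylation leaves no C on OT reads", {
  cfg <- tinyConfig(conversionRate = 1, methProb = c(0, 0, 0),
                    backgroundMethProb = 0, trnaMethProb = 0,
                    sequencingErrorRate = 0,
                    chipDepth = 300L, inputDepth = 50L)
  sim <- simulateReads(cfg, buildToyGenome(cfg))
  ot <- sim$chip$records$bs_strand == "OT" & !sim$chip$records$secondary
  expect_false(any(grepl("C", sim$chip$records$seq[ot])))
  ## and symmetric: OB plus-strand representation carries no G
  ob <- sim$chip$records$bs_strand == "OB" & !sim$chip$records$secondary
  expect_false(any(grepl("G", sim$chip$records$seq[ob])))
})

test_that("complete protection retains every CpG cytosine", {
  cfg <- tinyConfig(methProb = c(1, 1, 1), backgroundMethProb = 1,
                    trnaMethProb = 1, conversionFailureRate = 0,
                    conversionRate = 1, sequencingErrorRate = 0,
                    spikeInFraction = 0, chipDepth = 300L, inputDepth = 50L)
  toy <- buildToyGenome(cfg)
  sim <- simulateReads(cfg, toy)
  calls <- callCytosines(parseAlignments(sim$chip$records), toy$genome)
  cpg <- mcols(calls)$context == "CpG"
  expect_true(all(mcols(calls)$unmeth[cpg] == 0))
  expect_gt(sum(mcols(calls)$meth[cpg]), 0)
  ## all non-CpG cytosines converted
  expect_true(all(mcols(calls)$meth[!cpg] == 0))
})

test_that("spike-in read fraction is binomially consistent with the target", {
  cfg <- tinyConfig(chipDepth = 4000L, inputDepth = 0L,
                    spikeInFraction = 0.02)
  sim <- suppressWarnings(simulateReads(cfg, buildToyGenome(cfg)))
  frac <- mean(sim$chip$origins$spike_in)
  se <- sqrt(0.02 * 0.98 / 4000)
  expect_lt(abs(frac - 0.02), 3 * se)
})

test_that("ChIP enrichment at occupied loci approaches the configured fold", {
  cfg <- tinyConfig(chipDepth = 12000L, inputDepth = 12000L,
                    occupancyFold = 8, nOccupiedLoci = 6L,
                    spikeInFraction = 0)
  toy <- buildToyGenome(cfg)
  sim <- simulateReads(cfg, toy)
  occ <- toy$annotation[toy$annotation$element_id %in%
                        sim$occupiedLoci$element_id]
  inOcc <- function(origins) {
    mid <- origins$start + cfg@readLength / 2
    gr <- GRanges(origins$contig, IRanges(as.integer(mid) + 1L, width = 1L))
    sum(countOverlaps(gr, occ, ignore.strand = TRUE) > 0)
  }
  ratio <- (inOcc(sim$chip$origins) / nrow(sim$chip$origins)) /
           (inOcc(sim$input$origins) / nrow(sim$input$origins))
  expect_gt(ratio, 0.6 * 8)
  expect_lt(ratio, 1.4 * 8)
})

test_that("simulated CpG retention matches a direct Bernoulli oracle", {
  ## meth_prob 0.8 with complete conversion: fraction of retained Cs at
  ## CpGs converges to 0.8 within 3 binomial SE
  cfg <- tinyConfig(methProb = c(0.8, 0.8, 0.8), backgroundMethProb = 0.8,
                    trnaMethProb = 0.8, conversionRate = 1,
                    conversionFailureRate = 0, sequencingErrorRate = 0,
                    spikeInFraction = 0, chipDepth = 6000L, inputDepth = 0L)
  toy <- buildToyGenome(cfg)
  sim <- suppressWarnings(simulateReads(cfg, toy))
  calls <- callCytosines(parseAlignments(sim$chip$records), toy$genome)
  cpg <- mcols(calls)$context == "CpG"
  m <- sum(mcols(calls)$meth[cpg]); u <- sum(mcols(calls)$unmeth[cpg])
  n <- m + u
  expect_lt(abs(m / n - 0.8), 3 * sqrt(0.8 * 0.2 / n))
  ## independent oracle: a direct Bernoulli simulation at the same n
  set.seed(99)
  oracle <- mean(runif(round(n)) < 0.8)
  expect_lt(abs(m / n - oracle), 4 * sqrt(0.8 * 0.2 / n))
})

test_that("alignment-noise mode keeps one placement but records k", {
  cfg <- tinyConfig(chipDepth = 800L, inputDepth = 0L)
  toy <- buildToyGenome(cfg)
  sim <- suppressWarnings(simulateReads(cfg, toy, alignmentNoise = TRUE))
  rec <- sim$chip$records
  expect_false(any(rec$secondary))
  multi <- sim$chip$origins$n_valid_placements > 1
  expect_gt(sum(multi), 0)
  expect_true(all(rec$n_alignments[match(
    sim$chip$origins$read_id[multi], rec$read_id)] > 1))
})
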