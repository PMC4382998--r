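# Minimal PointData built straight from position/weight vectors.
makePd <- function(pos, w = rep(1, length(pos)), len = 10000,
                   contig = "chrT") {
  new("PointData", positions = setNames(list(as.numeric(pos)), contig),
      weights = setNames(list(as.numeric(w)), contig),
      librarySize = sum(w), peakShift = 0,
      contigLengths = setNames(len, contig))
}

test_that("point conversion shifts reads toward fragment midpoints", {
  rec <- recDf(c("p", "m"), "c1", c(1000L, 2000L), c("+", "-"),
               c("OT", "OB"), c(strrep("A", 50), strrep("A", 50)),
               contigLengths = c(c1 = 5000))
  pd <- toPointData(rec, peakShift = 116)
  expect_equal(pd@positions$c1, c(1000 + 58, 2050 - 58))
  ## zero shift: plus at start, minus at end
  pd0 <- toPointData(rec, peakShift = 0)
  expect_equal(pd0@positions$c1, c(1000, 2050))
  ## weight conservation through the conversion
  rec$weight <- c(0.25, 1)
  expect_equal(librarySize(toPointData(rec, 116)), 1.25)
  ## clipping to contig bounds
  recEdge <- recDf("e", "c1", 4990L, "+", "OT", strrep("A", 10),
                   contigLengths = c(c1 = 5000))
  recEdge$weight <- 1
  pdE <- toPointData(recEdge, peakShift = 400)
  expect_true(all(pdE@positions$c1 <= 4999))
})

test_that("window statistics match closed forms and the binomial tail", {
  ## equal library sizes (20 each); first window holds 20 chip vs 5 input
  chip <- makePd(rep(150, 20), len = 1200)
  input <- makePd(c(rep(150, 5), rep(1000, 15)), len = 1200)
  w <- scanWindows(chip, input, windowSize = 300, step = 300)
  first <- as.data.frame(w)[1, ]
  expect_equal(first$chip_sum, 20)
  expect_equal(first$input_sum, 5)
  ## pseudocount 0.5 on both sums (normalization is identity here)
  expect_equal(first$log2_ratio, log2(20.5 / 5.5))
  ## equal sums and equal library sizes give log2 = 0
  sym <- scanWindows(makePd(rep(10, 8), len = 600),
                     makePd(rep(10, 8), len = 600), 300, 300)
  expect_equal(as.data.frame(sym)$log2_ratio[1], 0)
  ## binomial p equals an explicit tail sum for 20 of 25 at p0 = 0.5
  tail20 <- sum(choose(25, 20:25) * 0.5^25)
  expect_equal(first$p_value, tail20, tolerance = 1e-12)
  expect_error(scanWindows(chip, input, windowSize = 0), "positive")
})

test_that("binomial p-values equal exact tail enumeration", {
  set.seed(21)
  for (i in 1:50) {
    k <- sample(0:200, 1); nI <- sample(0:200, 1)
    chip <- makePd(rep(100, max(k, 1))[seq_len(k)], len = 400)
    input <- makePd(rep(100, max(nI, 1))[seq_len(nI)], len = 400)
    if (k + nI == 0 || k == 0 || nI == 0) next
    p0 <- k / (k + nI)  # library-size null for these single-window libraries
    w <- as.data.frame(scanWindows(chip, input, 400, 400))
    xs <- k:(k + nI)
    enum <- sum(exp(lchoose(k + nI, xs) + xs * log(p0) +
                    (k + nI - xs) * log(1 - p0)))
    expect_equal(w$p_value[1], enum, tolerance = 1e-10)
  }
})

test_that("FDR attachment reproduces BH and swap-based empirical FDR", {
  mkWin <- function(p) {
    gr <- GRanges(rep("chrT", length(p)),
                  IRanges(start = seq_along(p) * 1000, width = 300))
    mcols(gr) <- S4Vectors::DataFrame(p_value = p, chip_sum = rep(1, length(p)),
                                      input_sum = rep(1, length(p)),
                                      log2_ratio = rep(1, length(p)))
    gr
  }
  ## single window: q_phred = -10 log10(p)
  w1 <- attachFDR(mkWin(0.01), mkWin(numeric(0)))
  expect_equal(mcols(w1)$q_phred, 20)
  ## BH step-up oracle: (0.01, 0.02, 0.04) -> (0.03, 0.03, 0.04)
  w3 <- attachFDR(mkWin(c(0.01, 0.02, 0.04)), mkWin(numeric(0)))
  expect_equal(10^(-mcols(w3)$q_phred / 10), c(0.03, 0.03, 0.04),
               tolerance = 1e-12)
  ## empirical FDR: 2 swapped vs 20 real at the cut -> 0.1 -> phred 10
  real <- mkWin(seq(0.001, 0.02, length.out = 20))
  swap <- mkWin(c(0.015, 0.02, 0.5, 0.9))
  wE <- attachFDR(real, swap)
  expect_equal(mcols(wE)$efdr_phred[20], 10, tolerance = 1e-9)
  ## zero swapped hits: numerator floored at 1, capped at phred 100
  expect_true(all(mcols(wE)$efdr_phred <= 100))
})

test_that("region making merges overlapping windows and reports the best", {
  mk <- function(starts, q, efdr, lr, p) {
    gr <- GRanges("chrT", IRanges(starts + 1L, width = 300))
    mcols(gr) <- S4Vectors::DataFrame(q_phred = q, efdr_phred = efdr,
                                      log2_ratio = lr, p_value = p)
    gr
  }
  ## no passing windows -> empty set
  expect_length(makeRegions(mk(0, 10, 20, 2, 0.1)), 0)
  ## two overlapping passing windows merge into one region
  w <- mk(c(0, 150), c(30, 40), c(20, 20), c(2, 2), c(0.01, 0.001))
  r <- makeRegions(w)
  expect_length(r, 1)
  expect_equal(start(r), 1L)
  expect_equal(end(r), 450L)
  expect_equal(mcols(r)$n_windows, 2L)
  expect_equal(mcols(r)$best_p, 0.001)
  ## monotonicity: raising any threshold shrinks the covered territory
  ## (the region count itself can rise by a split when a middle window
  ## drops out, so the sharp invariant is on width and window count)
  set.seed(31)
  wr <- mk(seq(0, 9000, 300), runif(31, 0, 80), runif(31, 0, 40),
           runif(31, -1, 3), runif(31))
  base <- makeRegions(wr, 20, 13, 1)
  for (thr in list(c(30, 13, 1), c(20, 20, 1), c(20, 13, 2))) {
    tighter <- makeRegions(wr, thr[1], thr[2], thr[3])
    expect_lte(sum(width(tighter)), sum(width(base)))
    expect_lte(sum(mcols(tighter)$n_windows), sum(mcols(base)$n_windows))
    expect_lte(length(tighter), sum(mcols(tighter)$n_windows))
  }
})

test_that("annotation intersection flags elements by >= 1 bp overlap", {
  ann <- GRanges("chrT", IRanges(c(101, 401, 1001), width = 100),
                 element_id = c("e1", "e2", "e3"),
                 class = c("SINE", "SINE", "tRNA"))
  ## region exactly spanning e1
  res <- intersectAnnotation(GRanges("chrT", IRanges(101, 200)), ann)
  expect_identical(mcols(res$elements)$enriched, c(TRUE, FALSE, FALSE))
  ## region overlapping e2 and e3 by 1 bp each
  res2 <- intersectAnnotation(GRanges("chrT", IRanges(500, 1001)), ann)
  expect_identical(mcols(res2$elements)$enriched, c(FALSE, TRUE, TRUE))
  sineRow <- res2$classCounts[res2$classCounts$class == "SINE", ]
  expect_identical(sineRow$n_enriched, 1L)
  ## empty region set -> zero tallies
  res0 <- intersectAnnotation(GRanges(), ann)
  expect_identical(sum(res0$classCounts$n_enriched), 0L)
})

test_that("element scoring agrees with window scoring on matched spans", {
  set.seed(41)
  chip <- makePd(sample(0:399, 120, replace = TRUE), len = 400)
  input <- makePd(sample(0:399, 100, replace = TRUE), len = 400)
  ann <- GRanges("chrT", IRanges(1, 400), element_id = "e1", class = "SINE")
  es <- scoreElements(ann, chip, input)
  w <- scanWindows(chip, input, windowSize = 400, step = 400)
  expect_equal(mcols(es)$chip_sum, mcols(w)$chip_sum)
  expect_equal(mcols(es)$input_sum, mcols(w)$input_sum)
  expect_equal(mcols(es)$occupancy_score, mcols(w)$log2_ratio)
  expect_equal(mcols(es)$p_value, mcols(w)$p_value)
  ## zero-coverage elements flagged with NA statistics
  annFar <- GRanges("chrT", IRanges(c(1, 395), width = 2),
                    element_id = c("a", "b"), class = "SINE")
  chipNear <- makePd(c(0, 1), len = 400)
  inputNear <- makePd(c(0, 1), len = 400)
  es2 <- scoreElements(annFar, chipNear, inputNear)
  expect_false(mcols(es2)$zero_coverage[1])
  expect_true(mcols(es2)$zero_coverage[2])
  expect_true(is.na(mcols(es2)$p_value[2]))
})

test_that("swapping libraries negates every log2 ratio", {
  set.seed(51)
  chip <- makePd(sample(0:9999, 400, replace = TRUE))
  input <- makePd(sample(0:9999, 300, replace = TRUE))
  w1 <- scanWindows(chip, input)
  w2 <- scanWindows(input, chip)
  expect_equal(mcols(w1)$log2_ratio, -mcols(w2)$log2_ratio)
})

test_that("occupied loci score higher than unoccupied loci in simulation", {
  cfg <- tinyConfig(chipDepth = 6000L, inputDepth = 6000L,
                    occupancyFold = 8, nOccupiedLoci = 6L)
  toy <- buildToyGenome(cfg)
  sim <- simulateReads(cfg, toy)
  pdC <- toPointData(parseAlignments(sim$chip$records), 116,
                     sim$contigLengths)
  pdI <- toPointData(parseAlignments(sim$input$records), 116,
                     sim$contigLengths)
  es <- scoreElements(toy$annotation, pdC, pdI)
  occ <- mcols(es)$element_id %in% sim$occupiedLoci$element_id
  ok <- !mcols(es)$zero_coverage
  expect_gt(mean(mcols(es)$occupancy_score[occ & ok]),
            mean(mcols(es)$occupancy_score[!occ & ok]) + 1)
})
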