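## Differential methylation between ChIP and input: Fisher windows in
## CpG-index space, per-element percent methylation, and per-class
## fractions of significantly enriched elements.

#' Two-sided Fisher exact test for 2x2 tables
#'
#' Vectorised two-sided Fisher exact p-values by hypergeometric tail
#' summation: with margins fixed, every table whose probability is at
#' most that of the observed table (ties included, up to a 1e-7 relative
#' tolerance guarding floating-point ties) contributes to p. Weighted
#' counts should be rounded half-up before testing. An all-zero table
#' returns p = 1 by convention.
#'
#' @param a,b,c,d Non-negative integer vectors: the table is
#'   `rbind(c(a, b), c(c, d))` (e.g. meth/unmeth x chip/input).
#' @return Numeric vector of two-sided p-values.
#' @examples
#' fisherExact2x2(5, 5, 5, 5)    # 1
#' fisherExact2x2(10, 0, 0, 10)  # == 2 / choose(20, 10)
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  out <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]; m2 <- c[i] + d[i]; k <- a[i] + c[i]
    if (m1 + m2 == 0) { out[i] <- 1; next }
    x <- max(0, k - m2):min(k, m1)
    px <- dhyper(x, m1, m2, k)
    pObs <- dhyper(a[i], m1, m2, k)
    out[i] <- min(1, sum(px[px <= pObs * (1 + 1e-7)]))
  }
  out
}

# Rolling sum over x of `win` consecutive entries (length(x)-win+1 values).
rollSum <- function(x, win) {
  cs <- cumsum(c(0, x))
  cs[(win + 1):length(cs)] - cs[1:(length(cs) - win)]
}

#' Test sliding CpG windows for methylation enrichment in ChIP vs input
#'
#' Joins the ChIP and input cytosine calls on shared CpG sites, slides a
#' window of `windowCpgs` consecutive CpG sites one site at a time along
#' each contig, and tests the pooled (methylated, unmethylated) x
#' (ChIP, input) table with the two-sided Fisher exact test. Windows
#' where either library has fewer than `minObs` total observations are
#' skipped. Benjamini-Hochberg correction is applied across tested
#' windows, and a window is reported when its phred FDR reaches
#' `fdrThresh` and its |log2 methylation ratio| reaches `log2Thresh`
#' (defaults 10 CpGs, 10 observations, phred 13, 0 - the published
#' window-test settings).
#'
#' Windows are defined in CpG-index space so that sparse-CpG regions
#' remain testable with fixed information per window; `mode = "bp"`
#' instead tiles fixed `windowBp`-wide windows over the covered CpGs.
#'
#' @param chipCalls,inputCalls [CytosineCalls-class] objects on the same
#'   reference.
#' @param windowCpgs CpG sites per window.
#' @param minObs Minimum weighted observations per library per window.
#' @param fdrThresh Phred-scaled BH FDR threshold for reporting.
#' @param log2Thresh Minimum |log2 methylation ratio| for reporting.
#' @param mode `"cpg"` (windows of `windowCpgs` sites) or `"bp"`.
#' @param windowBp Window width for `mode = "bp"`.
#' @return A [GenomicRanges::GRanges] of tested windows with counts,
#'   `log2_meth_ratio`, `direction` (`enriched`/`reduced`), `p_value`,
#'   `fdr_phred` and logical `reported`. Returns an empty result with
#'   attribute `reason` when no CpG site is covered in both libraries.
#' @export
testMethylationWindows <- function(chipCalls, inputCalls,
                                   windowCpgs = 10L, minObs = 10L,
                                   fdrThresh = 13, log2Thresh = 0,
                                   mode = c("cpg", "bp"), windowBp = 1000L) {
  mode <- match.arg(mode)
  sites <- joinCpgSites(chipCalls, inputCalls)
  empty <- GRanges()
  mcols(empty) <- DataFrame(chip_meth = numeric(0), chip_unmeth = numeric(0),
                            input_meth = numeric(0), input_unmeth = numeric(0),
                            n_cpgs = integer(0), log2_meth_ratio = numeric(0),
                            direction = character(0), p_value = numeric(0),
                            fdr_phred = numeric(0), reported = logical(0))
  if (!nrow(sites)) {
    attr(empty, "reason") <- "no CpG site covered in both libraries"
    return(empty)
  }
  win <- list()
  for (ctg in unique(sites$contig)) {
    s <- sites[sites$contig == ctg, , drop = FALSE]
    if (mode == "cpg") {
      if (nrow(s) < windowCpgs) next
      idx <- seq_len(nrow(s) - windowCpgs + 1L)
      win[[ctg]] <- data.frame(
        contig = ctg,
        start = s$pos[idx], end = s$pos[idx + windowCpgs - 1L] + 1L,
        n_cpgs = as.integer(windowCpgs),
        cm = rollSum(s$cm, windowCpgs), cu = rollSum(s$cu, windowCpgs),
        im = rollSum(s$im, windowCpgs), iu = rollSum(s$iu, windowCpgs))
    } else {
      bin <- s$pos %/% windowBp
      agg <- data.table::data.table(bin = bin, cm = s$cm, cu = s$cu,
                                    im = s$im, iu = s$iu)
      agg <- agg[, lapply(.SD, sum), by = "bin"]
      cnt <- data.table::data.table(bin = bin)[, list(n = .N), by = "bin"]
      win[[ctg]] <- data.frame(
        contig = ctg, start = agg$bin * windowBp,
        end = (agg$bin + 1L) * windowBp,
        n_cpgs = cnt$n[match(agg$bin, cnt$bin)],
        cm = agg$cm, cu = agg$cu, im = agg$im, iu = agg$iu)
    }
  }
  if (!length(win)) {
    attr(empty, "reason") <- "fewer covered CpG sites than one window"
    return(empty)
  }
  df <- do.call(rbind, win)
  tested <- df$cm + df$cu >= minObs & df$im + df$iu >= minObs
  df <- df[tested, , drop = FALSE]
  if (!nrow(df)) {
    attr(empty, "reason") <- "no window reaches the minimum observations"
    return(empty)
  }
  p <- fisherExact2x2(roundHalfUp(df$cm), roundHalfUp(df$cu),
                      roundHalfUp(df$im), roundHalfUp(df$iu))
  lr <- log2(((df$cm + 0.5) / (df$cm + df$cu + 1)) /
             ((df$im + 0.5) / (df$im + df$iu + 1)))
  fdr <- phredScale(p.adjust(p, method = "BH"))
  gr <- GRanges(df$contig, IRanges(df$start + 1L, df$end),
                chip_meth = df$cm, chip_unmeth = df$cu,
                input_meth = df$im, input_unmeth = df$iu,
                n_cpgs = df$n_cpgs, log2_meth_ratio = lr,
                direction = ifelse(lr >= 0, "enriched", "reduced"),
                p_value = p, fdr_phred = fdr,
                reported = fdr >= fdrThresh & abs(lr) >= log2Thresh)
  sort(gr, ignore.strand = TRUE)
}

# CpG sites (contig, pos, strand) with weighted counts in each library;
# site universe = union of covered CpG-context calls, ordered by position.
joinCpgSites <- function(chipCalls, inputCalls) {
  grab <- function(calls, prefix) {
    sel <- mcols(calls)$context == "CpG"
    data.table::data.table(
      contig = as.character(seqnames(calls))[sel],
      pos = start(calls)[sel] - 1L,
      strand = as.character(strand(calls))[sel],
      m = mcols(calls)$meth[sel], u = mcols(calls)$unmeth[sel])
  }
  cc <- grab(chipCalls); ic <- grab(inputCalls)
  data.table::setnames(cc, c("m", "u"), c("cm", "cu"))
  data.table::setnames(ic, c("m", "u"), c("im", "iu"))
  j <- merge(cc, ic, by = c("contig", "pos", "strand"), all = TRUE)
  for (col in c("cm", "cu", "im", "iu"))
    data.table::set(j, which(is.na(j[[col]])), col, 0)
  j <- j[(j$cm + j$cu > 0) | (j$im + j$iu > 0), ]
  data.table::setorderv(j, c("contig", "pos", "strand"))
  as.data.frame(j)
}

#' Percent methylation of annotated elements
#'
#' Pools the weighted CpG calls within each element's span:
#' `percent_meth = 100 * sum(meth) / sum(meth + unmeth)`. Elements with
#' no covered CpG are flagged, not scored.
#'
#' @param elements Element [GenomicRanges::GRanges].
#' @param calls A [CytosineCalls-class] object.
#' @return The elements with added metadata columns `meth_sum`,
#'   `total_sum`, `percent_meth` (`NA` when uncovered) and `covered`.
#' @export
scoreRegionMethylation <- function(elements, calls) {
  cpg <- calls[mcols(calls)$context == "CpG"]
  ov <- findOverlaps(cpg, elements, ignore.strand = TRUE)
  ms <- numeric(length(elements)); ts <- numeric(length(elements))
  if (length(ov)) {
    mAgg <- tapply(mcols(cpg)$meth[queryHits(ov)], subjectHits(ov), sum)
    tAgg <- tapply(callCoverage(cpg)[queryHits(ov)], subjectHits(ov), sum)
    idx <- as.integer(names(mAgg))
    ms[idx] <- mAgg
    ts[idx] <- tAgg
  }
  out <- elements
  mcols(out)$meth_sum <- ms
  mcols(out)$total_sum <- ts
  mcols(out)$percent_meth <- ifelse(ts > 0, 100 * ms / ts, NA_real_)
  mcols(out)$covered <- ts > 0
  out
}

#' Per-element methylation enrichment test, ChIP vs input
#'
#' For each element, pools the weighted CpG observations of both
#' libraries over the element span and applies the two-sided Fisher
#' exact test, BH-corrected across tested elements. An element is
#' significant when its phred FDR reaches `fdrThresh` with methylation
#' enriched in the ChIP (positive log2 ratio); this is the per-element
#' analogue of the window test used to ask what fraction of a class is
#' methylation-enriched in the ChIP.
#'
#' @param elements Element [GenomicRanges::GRanges].
#' @param chipCalls,inputCalls [CytosineCalls-class] objects.
#' @param minObs Minimum weighted observations per library for an
#'   element to be tested.
#' @param fdrThresh Phred-scaled BH FDR threshold.
#' @return The elements with metadata columns `chip_meth`,
#'   `chip_unmeth`, `input_meth`, `input_unmeth`, `log2_meth_ratio`,
#'   `p_value`, `fdr_phred`, `tested` and `significant`.
#' @export
testMethylationElements <- function(elements, chipCalls, inputCalls,
                                    minObs = 10L, fdrThresh = 13) {
  sc <- scoreRegionMethylation(elements, chipCalls)
  si <- scoreRegionMethylation(elements, inputCalls)
  cm <- mcols(sc)$meth_sum; cu <- mcols(sc)$total_sum - cm
  im <- mcols(si)$meth_sum; iu <- mcols(si)$total_sum - im
  tested <- (cm + cu) >= minObs & (im + iu) >= minObs
  p <- rep(NA_real_, length(elements))
  p[tested] <- fisherExact2x2(roundHalfUp(cm[tested]), roundHalfUp(cu[tested]),
                              roundHalfUp(im[tested]), roundHalfUp(iu[tested]))
  fdr <- rep(NA_real_, length(elements))
  fdr[tested] <- phredScale(p.adjust(p[tested], method = "BH"))
  lr <- log2(((cm + 0.5) / (cm + cu + 1)) / ((im + 0.5) / (im + iu + 1)))
  out <- elements
  mcols(out)$chip_meth <- cm; mcols(out)$chip_unmeth <- cu
  mcols(out)$input_meth <- im; mcols(out)$input_unmeth <- iu
  mcols(out)$log2_meth_ratio <- lr
  mcols(out)$p_value <- p
  mcols(out)$fdr_phred <- fdr
  mcols(out)$tested <- tested
  mcols(out)$significant <- tested & fdr >= fdrThresh & lr > 0
  out
}

#' Fraction of elements with significant methylation enrichment, by class
#'
#' Summarises [testMethylationElements()] output per annotation class:
#' the percentage of tested elements called significant (the
#' class-level comparison behind statements like "x% of SINEs are
#' methylation-enriched in the ChIP").
#'
#' @param elements Output of [testMethylationElements()] (needs `tested`
#'   and `significant` metadata columns).
#' @param classes Class label per element; defaults to the `class`
#'   metadata column.
#' @return A `data.frame` with `class`, `n_tested`, `n_significant` and
#'   `percent_significant`.
#' @export
fractionSignificant <- function(elements,
                                classes = mcols(elements)$class) {
  tested <- mcols(elements)$tested
  signif <- mcols(elements)$significant
  lv <- sort(unique(classes))
  nT <- vapply(lv, function(x) sum(tested & classes == x), integer(1))
  nS <- vapply(lv, function(x) sum(signif & classes == x), integer(1))
  data.frame(class = lv, n_tested = nT, n_significant = nS,
             percent_significant = ifelse(nT > 0, 100 * nS / nT, NA_real_),
             row.names = NULL)
}
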