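## Family-level statistics: Kruskal-Wallis across repeat families, Dunn's
## post-hoc pairwise comparisons, occupancy-vs-methylation moving-average
## curves and joint family summaries.

# Normalise group input: named list of numeric vectors.
asGroups <- function(x, g = NULL) {
  if (is.list(x)) {
    groups <- lapply(x, as.numeric)
    if (is.null(names(groups)))
      names(groups) <- paste0("group", seq_along(groups))
  } else {
    groups <- split(as.numeric(x), g)
  }
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (any(lengths(groups) == 0L))
    stop("every group must contain at least one observation")
  groups
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis test (via [stats::kruskal.test()]) with
#' the pooled mean ranks exposed, as needed by Dunn's post-hoc test and
#' by family-level reporting.
#'
#' @param x A list of numeric vectors (one per group), or a numeric
#'   vector accompanied by `g`.
#' @param g Group labels when `x` is a vector.
#' @return A list of class `KWResult`: `H` (tie-corrected statistic),
#'   `df`, `p_value`, `n` (group sizes) and `meanRanks`.
#' @examples
#' kw <- kruskalWallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' kw$H   # 27/7
#' @export
kruskalWallis <- function(x, g = NULL) {
  groups <- asGroups(x, g)
  if (length(groups) < 2L) stop("need at least two groups")
  values <- unlist(groups, use.names = FALSE)
  labels <- rep(names(groups), lengths(groups))
  kt <- kruskal.test(values, factor(labels, levels = names(groups)))
  r <- rank(values)
  structure(list(
    H = unname(kt$statistic), df = unname(kt$parameter),
    p_value = kt$p.value,
    n = lengths(groups),
    meanRanks = {
      mr <- tapply(r, factor(labels, levels = names(groups)), mean)
      setNames(as.numeric(mr), names(mr))
    }),
    class = "KWResult")
}

#' @export
print.KWResult <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.3g\n",
              x$H, x$df, x$p_value))
  cat("  mean ranks:",
      paste(sprintf("%s=%.2f (n=%d)", names(x$meanRanks), x$meanRanks,
                    x$n), collapse = ", "), "\n")
  invisible(x)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Follows a Kruskal-Wallis test with Dunn's z statistics on all group
#' pairs: `z = (Ri - Rj) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/ni + 1/nj))`
#' with `T = sum(t^3 - t)` over tie groups, two-sided normal p-values,
#' and multiplicity adjustment over the g(g-1)/2 pairs (Bonferroni by
#' default; `"holm"` and `"none"` also supported).
#'
#' @inheritParams kruskalWallis
#' @param method Adjustment method: `"bonferroni"`, `"holm"` or
#'   `"none"`.
#' @return A `data.frame` of class `DunnResult` with one row per pair:
#'   `group1`, `group2`, `z`, `p_value`, `p_adjusted`; the adjustment
#'   method is attached as attribute `method`.
#' @examples
#' dunnTest(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(2, 3, 4)))
#' @export
dunnTest <- function(x, g = NULL,
                     method = c("bonferroni", "holm", "none")) {
  method <- match.arg(method)
  groups <- asGroups(x, g)
  if (length(groups) < 2L) stop("need at least two groups")
  values <- unlist(groups, use.names = FALSE)
  labels <- rep(names(groups), lengths(groups))
  N <- length(values)
  r <- rank(values)
  meanRank <- tapply(r, factor(labels, levels = names(groups)), mean)
  n <- lengths(groups)
  ties <- table(values)
  tieTerm <- sum(ties^3 - ties) / (12 * (N - 1))
  var0 <- N * (N + 1) / 12 - tieTerm
  pairs <- utils::combn(names(groups), 2L)
  z <- apply(pairs, 2L, function(pr) {
    (meanRank[[pr[1]]] - meanRank[[pr[2]]]) /
      sqrt(var0 * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
  })
  z[!is.finite(z)] <- 0
  p <- 2 * pnorm(-abs(z))
  pAdj <- p.adjust(p, method = if (method == "none") "none" else method)
  out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    z = z, p_value = p, p_adjusted = pAdj)
  attr(out, "method") <- method
  class(out) <- c("DunnResult", "data.frame")
  out
}

#' Occupancy-vs-methylation moving-average curve
#'
#' Orders elements by methylation and returns the moving averages of
#' methylation and occupancy over contiguous blocks of `block` elements
#' sliding by one (default 25 data points per window); elements with a
#' missing value on either axis are excluded first. With n usable
#' elements the curve has n - block + 1 points.
#'
#' @param meth Numeric, methylation value per element (fraction or
#'   percent).
#' @param occupancy Numeric, occupancy score per element.
#' @param block Elements per moving-average block.
#' @return A `data.frame` with columns `meth` and `occupancy`, one row
#'   per block position.
#' @export
movingAverageCurve <- function(meth, occupancy, block = 25L) {
  ok <- !is.na(meth) & !is.na(occupancy)
  meth <- meth[ok]; occupancy <- occupancy[ok]
  if (length(meth) < block)
    stop("need at least `block` (", block, ") elements with values; got ",
         length(meth))
  o <- order(meth)
  data.frame(meth = zoo::rollmean(meth[o], block),
             occupancy = zoo::rollmean(occupancy[o], block))
}

#' Joint family-level summary of occupancy and methylation
#'
#' Builds the per-family comparison: group sizes, median/mean occupancy
#' score and percent methylation per family, and Kruskal-Wallis plus
#' Dunn tests on each axis. With `enrichedOnly = TRUE` the comparison is
#' restricted to elements flagged enriched/high-confidence upstream.
#'
#' @param elements A [GenomicRanges::GRanges] or `data.frame` carrying
#'   `family`, `occupancy_score` and `percent_meth` columns (e.g. the
#'   join of [scoreElements()] and [scoreRegionMethylation()] output).
#' @param enrichedOnly Logical; keep only elements whose
#'   `high_confidence` (or `enriched`) column is `TRUE`.
#' @param dunnMethod Adjustment method for [dunnTest()].
#' @return A list with `table` (per-family summary `data.frame`),
#'   `kwOccupancy`, `kwMethylation`, `dunnOccupancy`, `dunnMethylation`
#'   (NULL, with `reason`, when fewer than two families have data).
#' @export
familySummary <- function(elements, enrichedOnly = FALSE,
                          dunnMethod = "bonferroni") {
  df <- if (methods::is(elements, "GRanges"))
    as.data.frame(mcols(elements)) else as.data.frame(elements)
  if (enrichedOnly) {
    flag <- if ("high_confidence" %in% names(df)) df$high_confidence
            else df$enriched
    df <- df[flag %in% TRUE, , drop = FALSE]
  }
  need <- c("family", "occupancy_score", "percent_meth")
  if (!all(need %in% names(df)))
    stop("elements must carry columns: ", paste(need, collapse = ", "))
  fam <- df$family
  tab <- do.call(rbind, lapply(sort(unique(fam)), function(f) {
    sel <- fam == f
    data.frame(family = f, n = sum(sel),
               median_occupancy = stats::median(df$occupancy_score[sel],
                                                na.rm = TRUE),
               mean_occupancy = mean(df$occupancy_score[sel], na.rm = TRUE),
               median_percent_meth = stats::median(df$percent_meth[sel],
                                                   na.rm = TRUE),
               mean_percent_meth = mean(df$percent_meth[sel], na.rm = TRUE))
  }))
  axisTest <- function(col) {
    ok <- !is.na(df[[col]])
    fams <- unique(fam[ok])
    if (length(fams) < 2L)
      return(list(kw = NULL, dunn = NULL,
                  reason = "fewer than two families with data"))
    list(kw = kruskalWallis(df[[col]][ok], fam[ok]),
         dunn = dunnTest(df[[col]][ok], fam[ok], method = dunnMethod),
         reason = NULL)
  }
  occ <- axisTest("occupancy_score")
  met <- axisTest("percent_meth")
  list(table = tab,
       kwOccupancy = occ$kw, dunnOccupancy = occ$dunn,
       kwMethylation = met$kw, dunnMethylation = met$dunn,
       reason = c(occupancy = occ$reason, methylation = met$reason))
}
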