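# Two-group statistics.
#
# Test choice follows the convention of picking Student's t-test when both
# groups pass a normality check and the Mann-Whitney U-test otherwise;
# Shapiro-Wilk at alpha = 0.05 per group is the recorded normality rule.
# The Mann-Whitney p-value is exact -- full enumeration of group
# assignments over the pooled ranks, valid under ties -- for combined
# n <= 20, with the tie-corrected normal approximation above that. All
# tests are two-sided; no multiple-testing correction is applied (metrics
# are reported per comparison).

#' Exact Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U. For combined n <= `exactLimit` the p-value is
#' computed by full enumeration of all C(n, nA) assignments of the pooled
#' (midrank-tied) ranks, summing the probability of U values at least as
#' far from the null mean nA*nB/2 as observed; this stays exact under
#' ties. Larger samples use the normal approximation with tie correction
#' and continuity correction.
#'
#' @param a,b numeric samples.
#' @param exactLimit largest combined n for enumeration (default 20).
#' @return list(U, p, exact).
#' @export
mannWhitneyU <- function(a, b, exactLimit = 20L) {
  nA <- length(a); nB <- length(b); n <- nA + nB
  r <- rank(c(a, b))
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  mu <- nA * nB / 2
  if (n <= exactLimit) {
    idx <- combn(n, nA)
    rs <- matrix(r[idx], nrow = nA)
    Uall <- colSums(rs) - nA * (nA + 1) / 2
    p <- mean(abs(Uall - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p = p, exact = TRUE))
  }
  ties <- table(r)
  tieAdj <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(nA * nB / 12 * ((n + 1) - tieAdj))
  z <- (U - mu - sign(U - mu) * 0.5) / sigma
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
}

#' Percent difference relative to a reference mean
#'
#' `100 * (meanA - meanB) / meanA`, with group A the reference
#' (untreated/control) group; positive values report a reduction in the
#' comparison group.
#'
#' @param meanA reference group mean (non-zero).
#' @param meanB comparison group mean.
#' @return Percent difference.
#' @export
percentDifference <- function(meanA, meanB) {
  if (meanA == 0) stop("reference mean must be non-zero")
  100 * (meanA - meanB) / meanA
}

#' Compare two groups of measurements
#'
#' Assesses normality per group (Shapiro-Wilk at `alpha`; degenerate
#' constant samples count as non-normal), then runs a two-sided unpaired
#' Student's t-test if both groups look normal, otherwise an exact
#' two-sided Mann-Whitney U ([mannWhitneyU()]). Also reports group means,
#' SDs and the percent difference relative to group A.
#'
#' @param a,b numeric samples (n >= 3 each); `a` is the reference group.
#' @param labels group labels, reference first.
#' @param metricName measured quantity, recorded in the result.
#' @param policy "auto" (normality-gated), or force "t_test" /
#'   "mann_whitney".
#' @param alpha normality alpha (default 0.05).
#' @return A [GroupComparison-class].
#' @export
compareGroups <- function(a, b, labels = c("A", "B"),
                          metricName = "metric",
                          policy = c("auto", "t_test", "mann_whitney"),
                          alpha = 0.05) {
  policy <- match.arg(policy)
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs at least 3 values")
  swp <- function(x) {
    if (stats::sd(x) == 0) return(0)       # degenerate: not normal
    stats::shapiro.test(x)$p.value
  }
  normP <- c(swp(a), swp(b))
  useT <- switch(policy,
                 auto = all(normP > alpha),
                 t_test = TRUE,
                 mann_whitney = FALSE)
  if (useT) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    stat <- unname(tt$statistic); p <- tt$p.value
    testUsed <- "t_test"; exact <- NA
  } else {
    mw <- mannWhitneyU(a, b)
    stat <- mw$U; p <- mw$p
    testUsed <- "mann_whitney"; exact <- mw$exact
  }
  pd <- if (mean(a) == 0) NA_real_ else percentDifference(mean(a), mean(b))
  new("GroupComparison", metricName = metricName, labels = labels,
      nA = length(a), nB = length(b), means = c(mean(a), mean(b)),
      sds = c(stats::sd(a), stats::sd(b)), testUsed = testUsed,
      statistic = stat, pValue = p, percentDifference = pd,
      normalityP = normP, exact = isTRUE(exact))
}

#' Organ footprint on a gridded reference
#'
#' Overlays square grid cells on a 2D organ mask (e.g. the photographed
#' outline of a dissected organ on graph paper) and reports the percent
#' of cells covered, counting fractional coverage per cell.
#'
#' @param organMask2d logical matrix.
#' @param gridCellSize cell side, micrometres.
#' @param pixelSize micrometres per pixel (< gridCellSize).
#' @return A [GridAreaEstimate-class].
#' @export
gridAreaFraction <- function(organMask2d, gridCellSize, pixelSize) {
  if (gridCellSize <= pixelSize)
    stop("grid cell must be larger than a pixel")
  cpx <- max(1L, round(gridCellSize / pixelSize))
  nr <- nrow(organMask2d); nc <- ncol(organMask2d)
  gy <- ceiling(nr / cpx); gx <- ceiling(nc / cpx)
  covered <- 0
  for (i in seq_len(gy)) for (j in seq_len(gx)) {
    ys <- ((i - 1) * cpx + 1):min(i * cpx, nr)
    xs <- ((j - 1) * cpx + 1):min(j * cpx, nc)
    covered <- covered + mean(organMask2d[ys, xs])
  }
  new("GridAreaEstimate", percentArea = 100 * covered / (gy * gx),
      gridCellSize = gridCellSize, cellsTotal = gy * gx,
      cellsCovered = covered)
}

significanceStars <- function(p) {
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Build a per-metric two-group report
#'
#' Takes a long table of measurement records (one row per measurement)
#' and, for every metric present in both groups, runs [compareGroups()]
#' and collects a summary row with means, SDs, the test used, the
#' p-value, a significance annotation (*p<0.05 to ****p<0.0001) and the
#' percent difference relative to the reference group. Metrics missing or
#' underpowered (n < 3) in either group are skipped with a warning.
#' Optionally writes per-metric dot plots and a CSV/JSON summary.
#'
#' @param records data.frame with at least the columns named by
#'   `groupKey`, `metricKey` and `valueKey`.
#' @param groupKey,metricKey,valueKey column names (defaults "group",
#'   "metric", "value").
#' @param reference reference group label (default: first encountered).
#' @param outDir optional output directory for `summary.csv`,
#'   `summary.json` and one `<metric>.png` dot plot per metric.
#' @return list(comparisons = named list of
#'   [GroupComparison-class], summary = data.frame, skipped = character).
#' @export
buildReport <- function(records, groupKey = "group", metricKey = "metric",
                        valueKey = "value", reference = NULL,
                        outDir = NULL) {
  stopifnot(all(c(groupKey, metricKey, valueKey) %in% names(records)))
  grps <- unique(as.character(records[[groupKey]]))
  if (length(grps) < 2) stop("need at least 2 groups")
  if (!is.null(reference)) grps <- c(reference, setdiff(grps, reference))
  ga <- grps[1]; gb <- grps[2]
  metrics <- unique(as.character(records[[metricKey]]))
  comparisons <- list()
  skipped <- character(0)
  rows <- list()
  for (m in metrics) {
    sel <- records[[metricKey]] == m
    a <- records[[valueKey]][sel & records[[groupKey]] == ga]
    b <- records[[valueKey]][sel & records[[groupKey]] == gb]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 3 || length(b) < 3) {
      warning(sprintf("metric '%s' skipped: fewer than 3 values per group",
                      m))
      skipped <- c(skipped, m)
      next
    }
    cmp <- compareGroups(a, b, labels = c(ga, gb), metricName = m)
    comparisons[[m]] <- cmp
    rows[[m]] <- data.frame(
      metric = m, groupA = ga, groupB = gb, nA = cmp@nA, nB = cmp@nB,
      meanA = cmp@means[1], meanB = cmp@means[2], sdA = cmp@sds[1],
      sdB = cmp@sds[2], test = cmp@testUsed, statistic = cmp@statistic,
      p = cmp@pValue, significance = significanceStars(cmp@pValue),
      percentDifference = cmp@percentDifference)
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame()
  rownames(summary) <- NULL
  if (!is.null(outDir) && length(rows)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(summary, file.path(outDir, "summary.csv"),
              row.names = FALSE)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
    for (m in names(comparisons)) {
      sel <- records[[metricKey]] == m &
        as.character(records[[groupKey]]) %in% c(ga, gb)
      df <- data.frame(group = factor(records[[groupKey]][sel],
                                      levels = c(ga, gb)),
                       value = records[[valueKey]][sel])
      p <- ggplot2::ggplot(df, ggplot2::aes(x = group, y = value)) +
        ggplot2::geom_jitter(width = 0.12, alpha = 0.7, size = 1.6) +
        ggplot2::stat_summary(fun = mean, geom = "crossbar",
                              width = 0.4, linewidth = 0.4) +
        ggplot2::labs(title = sprintf("%s (%s, p = %.3g %s)", m,
                                      comparisons[[m]]@testUsed,
                                      comparisons[[m]]@pValue,
                                      significanceStars(
                                        comparisons[[m]]@pValue)),
                      x = NULL, y = m) +
        ggplot2::theme_classic()
      ggplot2::ggsave(file.path(outDir,
                                paste0(gsub("[^A-Za-z0-9_-]", "_", m),
                                       ".png")),
                      p, width = 3.2, height = 3.6, dpi = 150)
    }
  }
  list(comparisons = comparisons, summary = summary, skipped = skipped)
}
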