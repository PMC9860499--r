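# Dataset-level statistics: scale screening, windowed PCA, recall/AUC.

#' One-tail Welch test
#'
#' Welch's unequal-variances t statistic with Welch-Satterthwaite degrees of
#' freedom, returned as a one-tail p-value. With `direction = "auto"` the
#' tail is taken in the direction of the observed mean difference (identical
#' samples therefore give p = 0.5); `"greater"`/`"less"` test mean(x) >
#' mean(y) / mean(x) < mean(y).
#'
#' @param x,y numeric samples (each n >= 2)
#' @param direction `"auto"`, `"greater"` or `"less"`
#' @return one-tail p-value
#' @export
welchOneTail <- function(x, y, direction = c("auto", "greater", "less")) {
  direction <- match.arg(direction)
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("both samples have zero variance")
  if (direction == "auto")
    direction <- if (mean(x) >= mean(y)) "greater" else "less"
  stats::t.test(x, y, alternative = direction, var.equal = FALSE)$p.value
}

#' One-tail Mann-Whitney U test
#'
#' Rank-based two-sample test; exact enumeration when both samples are small
#' (min(n) <= 8, no ties), otherwise the normal approximation with tie
#' correction and continuity correction. Direction as in [welchOneTail()]
#' (auto = direction of the observed mean-rank difference; a perfectly
#' balanced U gives p = 0.5).
#'
#' @inheritParams welchOneTail
#' @return one-tail p-value
#' @export
mannWhitneyOneTail <- function(x, y, direction = c("auto", "greater", "less")) {
  direction <- match.arg(direction)
  nx <- length(x); ny <- length(y)
  u <- sum(rank(c(x, y))[seq_len(nx)]) - nx * (nx + 1) / 2
  if (direction == "auto") {
    if (u == nx * ny / 2) return(0.5)
    direction <- if (u > nx * ny / 2) "greater" else "less"
  }
  exact <- min(nx, ny) <= 8 && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = direction, exact = exact,
                       correct = TRUE)$p.value)
}

#' Screen property scales for class separation
#'
#' For every scale in a registry and every pair of sequence sets, computes
#' the per-sequence scale means, both one-tail tests, and the fraction of
#' scales reaching p < 0.05 per set pair. The first set named is the
#' reference: tails follow the direction of the reference set's observed
#' difference, matching how class-separation tables are conventionally
#' reported against the positive set.
#'
#' @param registry a [ScaleRegistry-class]
#' @param sets named list (>= 2) of character vectors of sequences
#' @param alpha significance threshold for the summary fractions
#' @return list with `comparisons` (data frame: scale, category, pair,
#'   mean/sd per set, welchP, mannWhitneyP) and `significantFraction`
#'   (per pair, per test)
#' @export
scaleScreen <- function(registry, sets, alpha = 0.05) {
  if (length(sets) < 2L) stop("need at least two sequence sets")
  setNamesV <- names(sets)
  means <- lapply(registry@scales, function(sc)
    lapply(sets, function(ss) vapply(ss, function(q) sequenceMean(sc, q),
                                     numeric(1), USE.NAMES = FALSE)))
  pairs <- utils::combn(setNamesV, 2, simplify = FALSE)
  rows <- list()
  for (nm in names(means)) {
    for (pr in pairs) {
      xa <- means[[nm]][[pr[1]]]; xb <- means[[nm]][[pr[2]]]
      rows[[length(rows) + 1L]] <- data.frame(
        scale = nm, category = registry@scales[[nm]]@category,
        setA = pr[1], setB = pr[2],
        meanA = mean(xa), sdA = stats::sd(xa),
        meanB = mean(xb), sdB = stats::sd(xb),
        welchP = tryCatch(welchOneTail(xa, xb), error = function(e) NA_real_),
        mannWhitneyP = tryCatch(mannWhitneyOneTail(xa, xb),
                                error = function(e) NA_real_))
    }
  }
  comparisons <- do.call(rbind, rows)
  pairKey <- paste(comparisons$setA, comparisons$setB, sep = " vs ")
  sig <- do.call(rbind, lapply(split(comparisons, pairKey), function(d)
    data.frame(pair = paste(d$setA[1], d$setB[1], sep = " vs "),
               welch = mean(d$welchP < alpha, na.rm = TRUE),
               mannWhitney = mean(d$mannWhitneyP < alpha, na.rm = TRUE))))
  rownames(sig) <- NULL
  list(comparisons = comparisons, significantFraction = sig)
}

#' Pick the best-separating scale per category
#'
#' From a [scaleScreen()] result, selects for each scale category the scale
#' with the smallest p-value (given test and set pair); ties break
#' alphabetically by scale name. This is the deterministic rule used to
#' assemble representative scales for the windowed PCA.
#'
#' @param screen result of [scaleScreen()]
#' @param setA,setB the set pair to rank on
#' @param test `"welch"` or `"mannWhitney"`
#' @return data frame: category, scale, p
#' @export
topScalePerCategory <- function(screen, setA, setB, test = c("welch", "mannWhitney")) {
  test <- match.arg(test)
  col <- if (test == "welch") "welchP" else "mannWhitneyP"
  d <- screen$comparisons
  d <- d[d$setA == setA & d$setB == setB & !is.na(d[[col]]), ]
  d <- d[order(d$category, d[[col]], d$scale), ]
  out <- d[!duplicated(d$category), c("category", "scale", col)]
  names(out)[3] <- "p"
  rownames(out) <- NULL
  out
}

#' PCA of windowed scale profiles
#'
#' Treats every 25-residue window of every input sequence as a sample and
#' the per-window means of the selected scales as features; features are
#' centered and scaled to unit variance before the decomposition. Constant
#' features are dropped with a warning. Returns the per-component variance
#' fractions (scree) and the feature loadings (rotation).
#'
#' @param sequences character vector (sequences shorter than the window are
#'   skipped)
#' @param scales list of [PropertyScale-class] (>= 2)
#' @param windowLength window size (default 25)
#' @return list: `varianceFraction`, `loadings`, `nWindows`, `dropped`
#' @export
pcaWindows <- function(sequences, scales, windowLength = 25L) {
  if (length(scales) < 2L) stop("need at least two scales")
  seqs <- as.character(sequences)
  seqs <- seqs[nchar(seqs) >= windowLength]
  feat <- lapply(scales, function(sc)
    unlist(lapply(seqs, function(s) windowProfile(sc, s, windowLength))))
  m <- do.call(cbind, feat)
  colnames(m) <- vapply(scales, function(s) s@name, character(1))
  if (nrow(m) < 3L) stop("need at least three windows in total")
  sds <- apply(m, 2, stats::sd)
  dropped <- colnames(m)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
    if (ncol(m) < 2L) stop("fewer than two non-constant features remain")
  }
  p <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  list(varianceFraction = vf, loadings = p$rotation, nWindows = nrow(m),
       dropped = dropped)
}

#' Recall-versus-recall curve and AUC
#'
#' Sweeps score thresholds over the union of both score sets and records
#' the fraction of the test set and of the comparison set retained
#' (score >= threshold) at each; the curve plots test retention against
#' comparison retention and the AUC is its trapezoidal area. Equivalent (up
#' to curve discretization, handled exactly here) to the rank statistic
#' `P(test > comparison) + 0.5 * P(tie)`, so a test set identical in
#' distribution to the comparison set gives 0.5 and a fully separated one
#' gives 1.
#'
#' @param testScores,comparisonScores numeric score vectors (non-empty)
#' @return list: `thresholds`, `testPct`, `comparisonPct` (both percent
#'   retained, nonincreasing in threshold), `auc`
#' @export
recallAUC <- function(testScores, comparisonScores) {
  if (!length(testScores) || !length(comparisonScores))
    stop("both score sets must be non-empty")
  thr <- sort(unique(c(testScores, comparisonScores)))
  testPct <- vapply(thr, function(t) mean(testScores >= t) * 100, numeric(1))
  compPct <- vapply(thr, function(t) mean(comparisonScores >= t) * 100,
                    numeric(1))
  # integrate test retention over comparison retention, from (100,100) to (0,0)
  x <- c(100, compPct, 0) / 100
  y <- c(100, testPct, 0) / 100
  auc <- sum(diff(-x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  list(thresholds = thr, testPct = testPct, comparisonPct = compPct,
       auc = auc)
}
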