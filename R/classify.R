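# The sliding-window F/P/D classifier.

#' Label a window from its (phi, alpha, v_model) triple
#'
#' A window is `F` when phi strictly exceeds the 0.08 cutoff. Otherwise it
#' is `D` when v_model lies on or above the P/D boundary
#' `v_model = -0.244 * alpha + 0.789` (points exactly on the boundary are
#' labeled D; the distance there is 0 either way), and `P` below it.
#'
#' @param phi,alpha,vModel numeric vectors (recycled to common length)
#' @param constants see [classifierConstants()]
#' @return character vector of labels in `{F, P, D}`
#' @export
windowLabel <- function(phi, alpha, vModel, constants = classifierConstants()) {
  boundary <- constants$pdSlope * alpha + constants$pdIntercept
  ifelse(phi > constants$phiCutoff, "F",
         ifelse(vModel >= boundary, "D", "P"))
}

#' Classifier distance of a window
#'
#' The normalized distance of a window into its class sector. For F windows
#' this is `(phi - 0.08) / (0.1164 - 0.08)`. For P and D windows it is the
#' Euclidean distance in the (alpha, v_model) plane from the window point to
#' the foot of its perpendicular on the P/D boundary, divided by 0.019 (the
#' boundary-to-training-set-mean distance). Values above 1 lie further from
#' the boundary than the training-set mean; the distance is continuous
#' through the boundary (it tends to 0 from both sides).
#'
#' @inheritParams windowLabel
#' @return nonnegative numeric vector
#' @export
classifierDistance <- function(phi, alpha, vModel,
                               constants = classifierConstants()) {
  lab <- windowLabel(phi, alpha, vModel, constants)
  m <- -constants$pdSlope                       # 0.244
  # foot of the perpendicular from (alpha, vModel) onto the boundary
  x <- (alpha / m + constants$pdIntercept - vModel) / (m + 1 / m)
  y <- (x - alpha) / m + vModel
  pd <- sqrt((alpha - x)^2 + (vModel - y)^2) / constants$pdNorm
  fDist <- (phi - constants$phiCutoff) /
    (constants$phiFoldedMean - constants$phiCutoff)
  ifelse(lab == "F", fDist, pd)
}

#' Classify every 25-residue window of a sequence
#'
#' Slides a 25-residue window in 1-residue steps, computing the window mean
#' hydrophobicity (phi), helix propensity (alpha) and v_model, then the
#' F/P/D label and classifier distance of each window. Applicable to
#' sequences with N > 25; for shorter sequences use the whole-sequence
#' descriptors ([polymerDescriptors()]).
#'
#' @param sequence amino-acid string (N > 25)
#' @param constants see [classifierConstants()]
#' @return a [ParSeClassification-class]
#' @export
classifyWindows <- function(sequence, constants = classifierConstants()) {
  s <- checkSequence(sequence)
  n <- nchar(s)
  w <- constants$windowLength
  if (n <= w)
    stop(sprintf(paste("sequence length %d: the window classifier requires",
                       "N > %d; use polymerDescriptors() for whole-sequence",
                       "descriptors"), n, w))
  chars <- strsplit(s, "")[[1]]
  phi <- .runningMean(unname(.PHI_VALUES[chars]), w)
  alpha <- .runningMean(unname(.HELIX_VALUES[chars]), w)
  f <- .runningMean(unname(.PPII_VALUES[chars]), w)
  q <- .runningMean(unname(.CHARGE_VALUES[chars]), w) * w
  rh <- .RH_R0 * w^(.RH_NU0 - .RH_NU_LNF * log(f)) +
    .RH_QNET * abs(q) - .RH_SQRTN * sqrt(w)
  v <- log(rh / .RH_R0) / log(w)
  lab <- windowLabel(phi, alpha, v, constants)
  dist <- classifierDistance(phi, alpha, v, constants)
  windows <- DataFrame(window = seq_along(phi),
                       center = seq_along(phi) + (w - 1L) %/% 2L,
                       phi = phi, alpha = alpha, vModel = v,
                       label = lab, distance = dist)
  new("ParSeClassification", sequence = s, windows = windows,
      residueLabels = .labelsToResidues(lab, n, w), constants = constants)
}

# Window label -> per-residue labels: window k labels its central residue
# k + (w-1)/2; terminal residues outside any window center inherit the first
# / last window's label.
.labelsToResidues <- function(windowLabels, n, w = 25L) {
  half <- (w - 1L) %/% 2L
  out <- character(n)
  out[seq_along(windowLabels) + half] <- windowLabels
  out[seq_len(half)] <- windowLabels[1L]
  out[(n - half + 1L):n] <- windowLabels[length(windowLabels)]
  out
}

# Accessors ------------------------------------------------------------------

#' Window table of a classification
#' @param object a [ParSeClassification-class]
#' @return `DataFrame` of per-window values
#' @export
windows <- function(object) object@windows

#' Per-residue labels
#' @inheritParams windows
#' @return character vector over `{F, P, D}`, length N
#' @export
residueLabels <- function(object) object@residueLabels

#' Per-residue classifier distances
#'
#' Window distances assigned to window centers, with the terminal residues
#' inheriting the first/last window's value (same scheme as the labels).
#' @inheritParams windows
#' @export
residueDistances <- function(object) {
  w <- object@constants$windowLength
  n <- nchar(object@sequence)
  half <- (w - 1L) %/% 2L
  d <- object@windows$distance
  out <- numeric(n)
  out[seq_along(d) + half] <- d
  out[seq_len(half)] <- d[1L]
  out[(n - half + 1L):n] <- d[length(d)]
  out
}

#' Summed P classifier distance
#'
#' The whole-protein phase-separation potential: the sum of classifier
#' distances over windows labeled P (F and D windows contribute nothing).
#' Zero exactly when no window is labeled P.
#'
#' @inheritParams windows
#' @return nonnegative numeric scalar
#' @export
summedPDistance <- function(object) {
  w <- object@windows
  sum(w$distance[w$label == "P"])
}

# Region calling -------------------------------------------------------------

#' Call contiguous single-class regions from a residue labeling
#'
#' Finds contiguous stretches of length >= `minLength` in which >= `purity`
#' of residues carry a single label. Seeds are the maximal pure runs of each
#' label; each seed is extended by absorbing adjacent runs (a mismatch run
#' together with the matching run beyond it) while the label fraction stays
#' at or above `purity`; same-label candidates whose union still satisfies
#' the purity are merged. Overlap between adjacent different-label regions
#' (possible through the tolerated label mixing) is split evenly, the odd
#' residue going to the N-terminal region.
#'
#' @param labels character vector of per-residue labels (from
#'   [residueLabels()]) or a [ParSeClassification-class]
#' @param minLength minimum region length (default 20)
#' @param purity minimum fraction of the region carrying its label
#'   (default 0.9)
#' @return an [IRanges::IRanges] with metadata column `label`, sorted by
#'   start, mutually non-overlapping
#' @export
callRegions <- function(labels, minLength = 20L, purity = 0.9) {
  if (is(labels, "ParSeClassification")) labels <- residueLabels(labels)
  n <- length(labels)
  runs <- rle(labels)
  rEnd <- cumsum(runs$lengths)
  rStart <- rEnd - runs$lengths + 1L
  nRuns <- length(rEnd)

  cand <- list()
  for (i in seq_len(nRuns)) {
    lab <- runs$values[i]
    lo <- i; hi <- i
    matchCount <- runs$lengths[i]
    repeat {
      ext <- .bestExtension(runs, lo, hi, lab, matchCount, purity)
      if (is.null(ext)) break
      lo <- ext$lo; hi <- ext$hi; matchCount <- ext$matchCount
    }
    len <- rEnd[hi] - rStart[lo] + 1L
    if (len >= minLength && matchCount / len >= purity)
      cand[[length(cand) + 1L]] <- list(start = rStart[lo], end = rEnd[hi],
                                        label = lab)
  }
  if (!length(cand)) return(IRanges())

  df <- unique(do.call(rbind, lapply(cand, as.data.frame)))
  df <- df[order(df$label, df$start), ]
  df <- .mergeSameLabel(df, labels, purity)
  df <- df[order(df$start, df$end), ]
  df <- .splitOverlaps(df)
  df <- df[df$end - df$start + 1L >= minLength, , drop = FALSE]
  IRanges(start = df$start, end = df$end,
          label = as.character(df$label))
}

# One extension step: try absorbing, on either side, the adjacent
# mismatch run together with the same-label run beyond it (or a terminal
# mismatch run alone); return the feasible extension with the higher
# resulting purity, ties to the left (N-terminal) side.
.bestExtension <- function(runs, lo, hi, lab, matchCount, purity) {
  rEnd <- cumsum(runs$lengths)
  rStart <- rEnd - runs$lengths + 1L
  len <- rEnd[hi] - rStart[lo] + 1L
  best <- NULL
  consider <- function(newLo, newHi, addedMatch) {
    newLen <- rEnd[newHi] - rStart[newLo] + 1L
    newMatch <- matchCount + addedMatch
    p <- newMatch / newLen
    if (p >= purity && (is.null(best) || p > best$p))
      best <<- list(lo = newLo, hi = newHi, matchCount = newMatch, p = p)
  }
  if (lo > 1L) {
    if (lo > 2L && runs$values[lo - 2L] == lab)
      consider(lo - 2L, hi, runs$lengths[lo - 2L])
    else
      consider(lo - 1L, hi, 0L)
  }
  if (hi < length(rEnd)) {
    if (hi < length(rEnd) - 1L && runs$values[hi + 2L] == lab)
      consider(lo, hi + 2L, runs$lengths[hi + 2L])
    else
      consider(lo, hi + 1L, 0L)
  }
  best
}

.mergeSameLabel <- function(df, labels, purity) {
  out <- df[0, ]
  for (lab in unique(df$label)) {
    sub <- df[df$label == lab, , drop = FALSE]
    i <- 1L
    while (i <= nrow(sub)) {
      j <- i
      while (j + 1L <= nrow(sub)) {
        s <- sub$start[i]; e <- max(sub$end[j + 1L], sub$end[j])
        if (sum(labels[s:e] == lab) / (e - s + 1L) >= purity) j <- j + 1L
        else break
      }
      out <- rbind(out, data.frame(start = sub$start[i],
                                   end = max(sub$end[i:j]), label = lab))
      i <- j + 1L
    }
  }
  out
}

.splitOverlaps <- function(df) {
  if (nrow(df) < 2L) return(df)
  # drop regions wholly contained in another
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df)))
    for (j in seq_len(nrow(df)))
      if (i != j && keep[j] && df$start[j] <= df$start[i] &&
          df$end[i] <= df$end[j] &&
          (df$end[j] - df$start[j]) > (df$end[i] - df$start[i]))
        keep[i] <- FALSE
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 2L) return(df)
  for (i in seq_len(nrow(df) - 1L)) {
    ov <- df$end[i] - df$start[i + 1L] + 1L
    if (ov > 0L) {
      toLeft <- (ov + 1L) %/% 2L                # odd overlap: extra to left
      df$end[i] <- df$start[i + 1L] + toLeft - 1L
      df$start[i + 1L] <- df$start[i + 1L] + toLeft
    }
  }
  df
}

#' Regions of a classification
#'
#' [callRegions()] applied to the per-residue labels, with a `score`
#' metadata column holding the mean per-residue classifier distance of each
#' region.
#'
#' @inheritParams windows
#' @return `IRanges` with metadata columns `label` and `score`
#' @export
regions <- function(object) {
  r <- callRegions(residueLabels(object),
                   minLength = object@constants$minRegionLength,
                   purity = object@constants$purity)
  if (length(r)) {
    d <- residueDistances(object)
    mcols(r)$score <- vapply(seq_along(r), function(i)
      mean(d[IRanges::start(r)[i]:IRanges::end(r)[i]]), numeric(1))
  }
  r
}

#' Longest called region of a given label
#' @inheritParams windows
#' @param label one of "P", "D", "F"
#' @return integer length in residues (0 when absent)
#' @export
longestRegion <- function(object, label = "P") {
  r <- regions(object)
  r <- r[mcols(r)$label == label]
  if (!length(r)) 0L else max(IRanges::width(r))
}

# Polar visualization --------------------------------------------------------

#' Homopolymer coordinates of the 20 amino acids
#'
#' v_model, beta-turn propensity, hydrophobicity and helix propensity of
#' each amino acid's homopolymer (default N = 100), plus its window label
#' under the classifier. The three-way split of this table is the
#' homopolymer class partition: residues labeled F are order promoting, D
#' disorder promoting, and P phase-separation promoting.
#'
#' @param n homopolymer length (default 100)
#' @return `DataFrame` with one row per amino acid
#' @export
homopolymerSpace <- function(n = 100L) {
  seqs <- vapply(AA_STANDARD, function(a) strrep(a, n), character(1))
  v <- vapply(seqs, vModel, numeric(1), USE.NAMES = FALSE)
  DataFrame(
    residue = AA_STANDARD,
    vModel = v,
    betaTurn = unname(.BETA_TURN_VALUES),
    phi = unname(.PHI_VALUES),
    alpha = unname(.HELIX_VALUES),
    label = windowLabel(unname(.PHI_VALUES), unname(.HELIX_VALUES), v))
}

#' Per-residue polar coordinates for sequence visualization
#'
#' Maps every residue of a sequence to the vector from the origin --- the
#' disordered-set mean point (v_model 0.558, beta-turn 1.101) --- to that
#' amino acid's homopolymer point in the (v_model, beta-turn) plane
#' (homopolymers of length `n`, default 100). Reported as magnitude and
#' angle (degrees, counterclockwise from the +v_model axis); the magnitude
#' is a per-type lookup, so it does not depend on sequence position.
#'
#' @param sequence amino-acid string
#' @param n homopolymer length for the reference coordinates
#' @return `DataFrame` with columns position, residue, magnitude, angleDeg
#' @export
vizPolar <- function(sequence, n = 100L) {
  chars <- .seqChars(sequence)
  hp <- homopolymerSpace(n)
  origin <- classifierConstants()$vizOrigin
  dv <- hp$vModel - origin[["vModel"]]
  dt <- hp$betaTurn - origin[["betaTurn"]]
  mag <- sqrt(dv^2 + dt^2)
  ang <- atan2(dt, dv) * 180 / pi
  idx <- match(chars, hp$residue)
  DataFrame(position = seq_along(chars), residue = chars,
            magnitude = mag[idx], angleDeg = ang[idx])
}

# Whole-protein scanning -----------------------------------------------------

#' Scan a set of sequences and summarize per protein
#'
#' Classifies every sequence and reports the whole-protein summary used for
#' proteome scans: the summed P classifier distance and the longest called
#' P, D and F region lengths. Optional interaction-potential coefficients
#' are applied with [applyPotentials()] before scoring. Sequences too short
#' for the window scheme (N <= 25) or failing the alphabet check yield a
#' row of `NA` summary values (with a message) so that record order and
#' count are preserved.
#'
#' @param sequences named character vector or `AAStringSet`
#' @param a,b,c interaction-potential coefficients (defaults 0 = plain
#'   classifier)
#' @param constants see [classifierConstants()]
#' @return `DataFrame`: id, N, summedP, longestP, longestD, longestF
#' @export
scanSequences <- function(sequences, a = 0, b = 0, c = 0,
                          constants = classifierConstants()) {
  seqs <- as.character(sequences)
  ids <- if (is.null(names(seqs))) as.character(seq_along(seqs)) else names(seqs)
  one <- function(s) {
    cl <- tryCatch(classifyWindows(s, constants), error = function(e) NULL)
    if (is.null(cl))
      return(c(summedP = NA_real_, longestP = NA_real_,
               longestD = NA_real_, longestF = NA_real_))
    if (a != 0 || b != 0 || c != 0) cl <- applyPotentials(cl, a, b, c)
    c(summedP = summedPDistance(cl),
      longestP = as.numeric(longestRegion(cl, "P")),
      longestD = as.numeric(longestRegion(cl, "D")),
      longestF = as.numeric(longestRegion(cl, "F")))
  }
  m <- t(vapply(seqs, one,
                c(summedP = 0, longestP = 0, longestD = 0, longestF = 0),
                USE.NAMES = FALSE))
  colnames(m) <- c("summedP", "longestP", "longestD", "longestF")
  nSkipped <- sum(is.na(m[, 1]))
  if (nSkipped > 0)
    message(nSkipped, " sequence(s) not classifiable (N <= 25 or nonstandard residues)")
  DataFrame(id = ids, N = nchar(seqs), summedP = m[, "summedP"],
            longestP = m[, "longestP"], longestD = m[, "longestD"],
            longestF = m[, "longestF"])
}
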