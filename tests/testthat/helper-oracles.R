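# Independent brute-force oracles used to validate the fast implementations.

# SCD by literal double loop over all residue pairs.
oracleSCD <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  q <- unname(c(K = 1, R = 1, D = -1, E = -1)[chars])
  q[is.na(q)] <- 0
  n <- length(chars)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      tot <- tot + q[i] * q[j] * sqrt(j - i)
  tot / n
}

# All maximal intervals of length >= minLength whose label-purity is
# >= purity for some label (an interval is maximal if no strict superset
# qualifies for the same label).
oracleRegions <- function(labels, minLength = 20L, purity = 0.9) {
  n <- length(labels)
  out <- list()
  for (lab in unique(labels)) {
    isLab <- cumsum(c(0L, labels == lab))
    qual <- list()
    for (s in seq_len(n - minLength + 1L))
      for (e in (s + minLength - 1L):n) {
        if ((isLab[e + 1L] - isLab[s]) / (e - s + 1L) >= purity)
          qual[[length(qual) + 1L]] <- c(s, e)
      }
    if (!length(qual)) next
    m <- do.call(rbind, qual)
    keep <- vapply(seq_len(nrow(m)), function(i)
      !any(m[, 1] <= m[i, 1] & m[i, 2] <= m[, 2] &
             (m[, 2] - m[, 1]) > (m[i, 2] - m[i, 1])), logical(1))
    m <- m[keep, , drop = FALSE]
    for (i in seq_len(nrow(m)))
      out[[length(out) + 1L]] <- data.frame(start = m[i, 1], end = m[i, 2],
                                            label = lab)
  }
  if (!length(out)) return(NULL)
  d <- do.call(rbind, out)
  d[order(d$start, d$end), ]
}

# AUC as the pairwise comparison statistic P(test > comp) + 0.5 P(tie).
oracleAUC <- function(test, comp) {
  tot <- 0
  for (t in test) tot <- tot + sum(t > comp) + 0.5 * sum(t == comp)
  tot / (length(test) * length(comp))
}

# Classic equal-variance two-sample t-test, one tail in the direction of
# the observed difference.
classicTOneTail <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  stats::pt(abs(t), df = nx + ny - 2, lower.tail = FALSE)
}

# Exact one-tail Mann-Whitney p by enumeration of all group assignments.
oracleMWExact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  if (uObs >= nx * ny / 2) mean(us >= uObs) else mean(us <= uObs)
}

# Literal five-term evaluation of the weighted pi-contact potential.
oracleUPi <- function(window, a = 1) {
  chars <- strsplit(toupper(window), "")[[1]]
  nY <- sum(chars == "Y"); nR <- sum(chars == "R")
  nF <- sum(chars == "F"); nK <- sum(chars == "K")
  dv <- function(c1, c2) if (c1 == c2) 1 else abs(c1 - c2)
  a * (3 * nY * nR / dv(nY, nR) + 2 * nY * nK / dv(nY, nK) +
         2 * nF * nR / dv(nF, nR) + 1 * nF * nK / dv(nF, nK) +
         1 * nF * nY / dv(nF, nY))
}

# Random standard-alphabet sequence.
randomSeq <- function(n, prob = NULL) {
  paste(sample(AA_STANDARD, n, replace = TRUE, prob = prob), collapse = "")
}

# A sample with exactly the requested mean and SD (deterministic shape).
momentMatchedSample <- function(n, mean, sd) {
  z <- stats::qnorm(stats::ppoints(n))
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}
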