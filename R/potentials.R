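# Pairwise-interaction corrections to the classifier, parameter fitting,
# and van't Hoff analysis of saturation-concentration series.

#' Pi-contact interaction potential of a window
#'
#' Counts Tyr/Phe x Arg/Lys (and Phe x Tyr) pairings with the 3:2:1
#' weighting that mimics the experimental cohesion rank order
#' Tyr-Arg > Tyr-Lys ~ Phe-Arg > Phe-Lys:
#' `a * (3*t(Y,R) + 2*t(Y,K) + 2*t(F,R) + 1*t(F,K) + 1*t(F,Y))` where each
#' pair term is `count1*count2 / |count1 - count2|`, the divisor replaced by
#' 1 when the counts are equal. (The absolute value keeps every term
#' nonnegative, as the rank-order rationale requires.) The potential grows
#' with aromatic/cationic content and is largest when interaction partners
#' are present at similar counts.
#'
#' @param window amino-acid string (one classifier window; any length
#'   accepted, the classifier applies it per 25-residue window)
#' @param a scale coefficient (default 1)
#' @return nonnegative numeric (0 when `a = 0` or no Y/F/R/K present)
#' @export
uPi <- function(window, a = 1) {
  chars <- .seqChars(window)
  cnt <- function(x) sum(chars == x)
  y <- cnt("Y"); r <- cnt("R"); k <- cnt("K"); f <- cnt("F")
  term <- function(c1, c2) c1 * c2 / max(abs(c1 - c2), 1L)
  a * (3 * term(y, r) + 2 * term(y, k) + 2 * term(f, r) +
         1 * term(f, k) + 1 * term(f, y))
}

#' Charge interaction potential of a window
#'
#' `Uq = b * SCD + c * |NCPR|`, evaluated per window. The SCD term carries
#' the sign of the sequence charge decoration (typically negative for
#' well-mixed opposite charges), the NCPR term is nonnegative.
#'
#' @inheritParams uPi
#' @param b,c fitting coefficients
#' @export
uQ <- function(window, b, c) b * scd(window) + c * abs(ncpr(window))

# Per-window correction features of a classification, for fast fitting:
# the unit-coefficient u_pi, scd and |ncpr| of every window plus the
# original labels and distances.
.windowFeatures <- function(object) {
  s <- object@sequence
  w <- object@constants$windowLength
  win <- object@windows
  sub <- substring(s, win$window, win$window + w - 1L)
  list(label = win$label,
       d0 = win$distance,
       pi1 = vapply(sub, uPi, numeric(1), a = 1, USE.NAMES = FALSE),
       scd = vapply(sub, scd, numeric(1), USE.NAMES = FALSE),
       nabs = vapply(sub, function(x) abs(ncpr(x)), numeric(1),
                     USE.NAMES = FALSE))
}

.potentialFromFeatures <- function(feat, a, b, c) {
  u <- a * feat$pi1 + b * feat$scd + c * feat$nabs
  isP <- feat$label == "P"
  isD <- feat$label == "D"
  sum(feat$d0[isP] + u[isP]) + sum(pmax(u[isD] - feat$d0[isD], 0))
}

#' Apply interaction potentials to a classification
#'
#' The combined per-window correction `U = U_pi + U_q` is added to the
#' classifier distance of every P-labeled window. D-labeled windows flip to
#' P when `U` exceeds their original classifier distance, taking
#' `U - original distance` as their new distance; F windows are untouched.
#' With `a = b = c = 0` the classification is returned unchanged.
#'
#' @param object a [ParSeClassification-class]
#' @param a pi-potential coefficient
#' @param b,c charge-potential coefficients
#' @return a new `ParSeClassification` with corrected labels/distances (the
#'   applied coefficients are recorded in `constants$potentials`)
#' @export
applyPotentials <- function(object, a = 0, b = 0, c = 0) {
  win <- object@windows
  feat <- .windowFeatures(object)
  u <- a * feat$pi1 + b * feat$scd + c * feat$nabs
  lab <- win$label
  d <- win$distance
  isP <- lab == "P"
  d[isP] <- d[isP] + u[isP]
  flip <- lab == "D" & u > win$distance
  d[flip] <- u[flip] - win$distance[flip]
  lab[flip] <- "P"
  win$label <- lab
  win$distance <- pmax(d, 0)
  consts <- object@constants
  consts$potentials <- c(a = a, b = b, c = c)
  n <- nchar(object@sequence)
  new("ParSeClassification", sequence = object@sequence, windows = win,
      residueLabels = .labelsToResidues(lab, n, consts$windowLength),
      constants = consts)
}

#' Corrected phase-separation potential of a sequence
#'
#' [classifyWindows()] followed by [applyPotentials()] and
#' [summedPDistance()].
#'
#' @param sequence amino-acid string (N > 25)
#' @inheritParams applyPotentials
#' @return numeric scalar
#' @export
psPotential <- function(sequence, a = 0, b = 0, c = 0) {
  .potentialFromFeatures(.windowFeatures(classifyWindows(sequence)), a, b, c)
}

# van't Hoff ------------------------------------------------------------------

#' Phase-separation thermodynamics from a c_sat(T) series
#'
#' At coexistence, `dg = R*T*ln(c_dilute/c_dense)`, so
#' `ln(c_sat/c_dense) = (dh/R)*(1/T) - ds/R`; a least-squares fit of
#' `ln(c_sat)` against `1/T` yields the standard molar enthalpy and entropy
#' of transferring a chain out of the condensed phase. `dg` is reported at
#' 273.15 K and satisfies `dg = dh - T*ds` identically.
#'
#' @param temperature temperatures in Kelvin (>= 2 distinct values)
#' @param csat dilute-phase (saturation) concentrations, M
#' @param cDense condensed-phase concentration, M (0.03 for A1-LCD-like,
#'   0.01 for Ddx4-like systems)
#' @return list with `dh` (kJ/mol), `ds` (kJ/mol/K), `dg` (kJ/mol at
#'   273.15 K), `cDense`, and `residual` (RMS of the fit in ln-c units)
#' @export
vantHoff <- function(temperature, csat, cDense) {
  if (length(temperature) != length(csat))
    stop("temperature and csat must have equal length")
  if (length(unique(temperature)) < 2L)
    stop("van't Hoff analysis needs at least two distinct temperatures")
  if (any(csat <= 0) || cDense <= 0)
    stop("concentrations must be positive")
  y <- log(csat / cDense)
  x <- 1 / temperature
  fit <- stats::lm(y ~ x)
  dh <- unname(stats::coef(fit)[2]) * .GAS_R / 1000     # kJ/mol
  ds <- -unname(stats::coef(fit)[1]) * .GAS_R / 1000    # kJ/mol/K
  list(dh = dh, ds = ds, dg = dh - .THERMO_T0 * ds, cDense = cDense,
       residual = sqrt(mean(stats::residuals(fit)^2)))
}

# Fitting ----------------------------------------------------------------------

.METRICS <- c("dh", "ds", "dg", "csat")

.mutantFeatures <- function(mutants) {
  lapply(mutants$sequence, function(s)
    .windowFeatures(classifyWindows(s)))
}

.potentialsAll <- function(featList, a, b, c)
  vapply(featList, .potentialFromFeatures, numeric(1), a = a, b = b, c = c)

.checkObservable <- function(obs) {
  if (any(!is.finite(obs))) stop("observable contains non-finite values")
  if (stats::sd(obs) == 0) stop("observable is constant; nothing to fit")
}

#' Subset mutants whose charge properties match the wild type
#'
#' Keeps records with NCPR and SCD equal to the wild-type values (within a
#' small numeric tolerance). Used to isolate the pi-contact coefficient,
#' which must be fit on variants whose charge and charge patterning are
#' unchanged.
#'
#' @param mutants data frame with columns `id` and `sequence`
#' @param wtId id of the wild-type record (default `"WT"`)
#' @param tol numeric tolerance
#' @export
filterChargeMatched <- function(mutants, wtId = "WT", tol = 1e-9) {
  if (!wtId %in% mutants$id) stop("wild-type record not found: ", wtId)
  wt <- mutants$sequence[mutants$id == wtId][1]
  keep <- vapply(mutants$sequence, function(s)
    abs(ncpr(s) - ncpr(wt)) < tol && abs(scd(s) - scd(wt)) < tol,
    logical(1))
  mutants[keep, , drop = FALSE]
}

#' Fit the pi-potential coefficient
#'
#' One-dimensional grid search (with one refinement pass at ten-fold finer
#' step around the best grid point) for the `a` maximizing the absolute
#' Pearson correlation between the corrected potential and the chosen
#' observable. Ties take the smallest `a`. The caller restricts `mutants`
#' to charge-matched variants (see [filterChargeMatched()]); at least three
#' records with finite observable are required.
#'
#' @param mutants data frame with columns `sequence` and the observable
#'   named by `metric`
#' @param metric one of `"dh"`, `"ds"`, `"dg"`, `"csat"`
#' @param grid candidate values (default `seq(0, 1, by = 0.01)`)
#' @param refine refinement factor (default 10; 0 or 1 disables)
#' @return list with `a`, signed Pearson `r` at the optimum, and the
#'   search `grid`/`objective`
#' @export
fitA <- function(mutants, metric = "dh", grid = seq(0, 1, by = 0.01),
                 refine = 10) {
  metric <- match.arg(metric, .METRICS)
  obs <- mutants[[metric]]
  if (is.null(obs) || sum(is.finite(obs)) < 3L)
    stop("need >= 3 mutants with finite '", metric, "'")
  .checkObservable(obs)
  feats <- .mutantFeatures(mutants)
  objective <- function(a) stats::cor(.potentialsAll(feats, a, 0, 0), obs)
  rs <- vapply(grid, objective, numeric(1))
  best <- grid[which.max(abs(rs))]             # which.max: first max = smallest a
  if (refine > 1) {
    step <- if (length(grid) > 1) min(diff(sort(grid))) else 0
    if (step > 0) {
      fine <- seq(max(min(grid), best - step), min(max(grid), best + step),
                  by = step / refine)
      rsF <- vapply(fine, objective, numeric(1))
      if (max(abs(rsF)) > max(abs(rs))) best <- fine[which.max(abs(rsF))]
    }
  }
  rBest <- objective(best)
  if (abs(rBest) < 0.2)
    warning("weak correlation (|r| = ", round(abs(rBest), 3),
            "): observable may be unrelated to the potential")
  list(a = best, r = rBest, grid = grid, objective = rs)
}

#' Fit the charge-potential coefficients
#'
#' Two-dimensional grid search over `(b, c)` (refined ten-fold around the
#' best point) maximizing the absolute Pearson correlation between the
#' corrected potential (with `a` held fixed) and the observable. Ties take
#' the first (smallest `b`, then smallest `c`) grid point.
#'
#' @inheritParams fitA
#' @param a fixed pi-potential coefficient (from [fitA()])
#' @param bGrid,cGrid candidate values (defaults `seq(-50, 50, by = 0.2)`)
#' @return list with `b`, `c`, signed `r`
#' @export
fitBC <- function(mutants, metric = "dh", a = 0,
                  bGrid = seq(-50, 50, by = 0.2),
                  cGrid = seq(-50, 50, by = 0.2), refine = 10) {
  metric <- match.arg(metric, .METRICS)
  obs <- mutants[[metric]]
  if (is.null(obs) || sum(is.finite(obs)) < 3L)
    stop("need >= 3 mutants with finite '", metric, "'")
  .checkObservable(obs)
  feats <- .mutantFeatures(mutants)
  # flatten features across mutants for vectorized grid evaluation
  grp <- rep(seq_along(feats), vapply(feats, function(f) length(f$d0),
                                      integer(1)))
  lab <- unlist(lapply(feats, `[[`, "label"))
  d0 <- unlist(lapply(feats, `[[`, "d0"))
  pi1 <- unlist(lapply(feats, `[[`, "pi1"))
  scdW <- unlist(lapply(feats, `[[`, "scd"))
  naW <- unlist(lapply(feats, `[[`, "nabs"))
  isP <- lab == "P"; isD <- lab == "D"
  basePot <- as.vector(rowsum(d0[isP], grp[isP],
                              reorder = TRUE)[as.character(seq_along(feats)), 1])
  basePot[is.na(basePot)] <- 0
  evalGrid <- function(bs, cs) {
    bestVal <- -Inf; bestB <- bs[1]; bestC <- cs[1]
    for (b in bs) {
      uPart <- a * pi1 + b * scdW
      for (cc in cs) {
        u <- uPart + cc * naW
        pot <- basePot
        add <- rowsum(c(u[isP], pmax(u[isD] - d0[isD], 0)),
                      c(grp[isP], grp[isD]))
        pot[as.integer(rownames(add))] <- pot[as.integer(rownames(add))] + add[, 1]
        r <- abs(stats::cor(pot, obs))
        if (is.finite(r) && r > bestVal + 1e-12) {
          bestVal <- r; bestB <- b; bestC <- cc
        }
      }
    }
    list(b = bestB, c = bestC, val = bestVal)
  }
  top <- evalGrid(bGrid, cGrid)
  if (refine > 1) {
    sb <- if (length(bGrid) > 1) min(diff(sort(bGrid))) else 0
    sc <- if (length(cGrid) > 1) min(diff(sort(cGrid))) else 0
    if (sb > 0 && sc > 0) {
      fineB <- seq(top$b - sb, top$b + sb, by = sb / refine)
      fineC <- seq(top$c - sc, top$c + sc, by = sc / refine)
      fine <- evalGrid(fineB, fineC)
      if (fine$val > top$val) top <- fine
    }
  }
  pot <- .potentialsAll(feats, a, top$b, top$c)
  list(b = top$b, c = top$c, r = stats::cor(pot, obs))
}

#' Directional agreement of predicted and observed mutation effects
#'
#' Fraction of mutants whose predicted change in phase-separation potential
#' relative to the wild type has the same direction as the experimental
#' change. The experimental direction is the observable's change multiplied
#' by `observableSign`, which encodes how the observable relates to
#' phase-separation strength; defaults: `csat` -1 (lower saturation
#' concentration = stronger), `dg` -1, `dh` -1 (more exothermic =
#' stronger), `ds` +1. Mutants with a zero change on either axis are
#' excluded from the denominator.
#'
#' @inheritParams fitA
#' @param a,b,c potential coefficients
#' @param wtId id of the wild-type record
#' @param observableSign +1 or -1; `NULL` picks the documented default for
#'   `metric`
#' @return list with `fraction`, `agree`, `total` (counted mutants), and
#'   `excluded`
#' @export
directionalAgreement <- function(mutants, metric = "dh", a = 0, b = 0, c = 0,
                                 wtId = "WT", observableSign = NULL) {
  metric <- match.arg(metric, .METRICS)
  if (is.null(observableSign))
    observableSign <- c(dh = -1, ds = 1, dg = -1, csat = -1)[[metric]]
  if (!wtId %in% mutants$id) stop("wild-type record not found: ", wtId)
  obs <- mutants[[metric]]
  pred <- .potentialsAll(.mutantFeatures(mutants), a, b, c)
  wi <- which(mutants$id == wtId)[1]
  dPred <- pred[-wi] - pred[wi]
  dObs <- (obs[-wi] - obs[wi]) * observableSign
  usable <- dPred != 0 & dObs != 0 & is.finite(dObs)
  agree <- sum(sign(dPred[usable]) == sign(dObs[usable]))
  list(fraction = if (any(usable)) agree / sum(usable) else NA_real_,
       agree = agree, total = sum(usable), excluded = sum(!usable))
}

#' Read a mutant table
#'
#' Tab-separated table with columns `id`, `sequence`, optional `family`,
#' optional observables `dh`, `ds`, `dg` (kJ/mol), and optional wide
#' saturation-concentration columns named `csat@<T>` (T in Kelvin,
#' concentrations in M). Returns the table plus a long-format c_sat series
#' (id, temperature, csat) for [vantHoff()].
#'
#' @param path TSV path
#' @return list(`table`, `csat`)
#' @export
readMutantTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("id", "sequence") %in% names(df)))
    stop("mutant table needs 'id' and 'sequence' columns")
  csatCols <- grep("^csat@", names(df), value = TRUE)
  long <- NULL
  if (length(csatCols)) {
    temps <- as.numeric(sub("^csat@", "", csatCols))
    if (any(is.na(temps))) stop("csat@<T> columns must carry numeric Kelvin temperatures")
    long <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
      v <- as.numeric(df[i, csatCols])
      ok <- is.finite(v)
      if (!any(ok)) return(NULL)
      data.frame(id = df$id[i], temperature = temps[ok], csat = v[ok])
    }))
  }
  list(table = df[, setdiff(names(df), csatCols), drop = FALSE], csat = long)
}
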