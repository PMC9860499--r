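# Deterministic generators of synthetic sequences and observables with the
# statistical structure the analyses assume, so every test runs offline.

# Run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Homopolymer sequences of the 20 standard amino acids
#' @param n length of each homopolymer (default 100)
#' @return named character vector of 20 sequences
#' @export
makeHomopolymers <- function(n = 100L) {
  out <- vapply(AA_STANDARD, function(a) strrep(a, n), character(1))
  names(out) <- AA_STANDARD
  out
}

# Residue-sampling profiles for block copolymers: enriched for the three
# window classes.
.BLOCK_PROFILES <- list(
  ps = c(N = 0.22, S = 0.24, G = 0.26, T = 0.12, Q = 0.08, Y = 0.04,
         A = 0.04),
  id = c(E = 0.22, K = 0.20, P = 0.16, Q = 0.12, A = 0.12, R = 0.10,
         D = 0.08),
  folded = c(W = 0.10, F = 0.16, I = 0.18, L = 0.20, V = 0.18, Y = 0.08,
             M = 0.05, C = 0.05))

#' Synthetic block copolymer
#'
#' Concatenates blocks of residues sampled i.i.d. from named composition
#' profiles (`"ps"`, `"id"`, `"folded"`) or from user-supplied probability
#' vectors, emulating multi-domain proteins whose domains belong to
#' different window classes.
#'
#' @param blocks list of `list(composition=, length=)`; `composition` is a
#'   profile name or a named probability vector over one-letter codes
#' @param seed RNG seed
#' @return a single sequence string; block boundaries in attribute `blocks`
#' @export
makeBlockCopolymer <- function(blocks, seed = 1L) {
  .withSeed(seed, {
    parts <- vapply(blocks, function(b) {
      p <- b$composition
      if (is.character(p) && length(p) == 1L) p <- .BLOCK_PROFILES[[p]]
      if (is.null(p)) stop("unknown composition profile")
      paste(sample(names(p), b$length, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
    seqOut <- paste(parts, collapse = "")
    ends <- cumsum(nchar(parts))
    attr(seqOut, "blocks") <- data.frame(start = c(1L, head(ends, -1L) + 1L),
                                         end = ends)
    seqOut
  })
}

#' Synthetic folded / disordered / phase-separating sequence sets
#'
#' Draws three sets of sequences whose residue compositions emulate the
#' three protein-region classes. Each sequence's composition is a Dirichlet
#' draw around a frozen class profile (see `R/fixtures-profiles.R`; profiles
#' were calibrated once, by the committed `scripts/tune_compositions.R`, so
#' that set means of v_model and beta-turn propensity land on the class
#' values with realistic between-sequence spread) and its residues are
#' sampled i.i.d. from that draw.
#'
#' @param n named integer vector: sequences per set (defaults
#'   `c(psid = 224, id = 121, folded = 421)`, the curated-set sizes)
#' @param seed RNG seed
#' @return named list of three named character vectors (`psid`, `id`,
#'   `folded`)
#' @export
makeCompositionSets <- function(n = c(psid = 224L, id = 121L, folded = 421L),
                                seed = 1L) {
  stopifnot(all(c("psid", "id", "folded") %in% names(n)))
  .withSeed(seed, {
    out <- lapply(c("psid", "id", "folded"), function(cls) {
      cfg <- .CLASS_PROFILES[[cls]]
      seqs <- vapply(seq_len(n[[cls]]), function(i) {
        len <- sample(cfg$lengthRange[1]:cfg$lengthRange[2], 1L)
        g <- stats::rgamma(20L, shape = cfg$profile * cfg$concentration)
        if (sum(g) == 0) g <- cfg$profile
        paste(sample(AA_STANDARD, len, replace = TRUE, prob = g / sum(g)),
              collapse = "")
      }, character(1))
      names(seqs) <- sprintf("%s_%03d", cls, seq_len(n[[cls]]))
      seqs
    })
    names(out) <- c("psid", "id", "folded")
    out
  })
}

#' Charge-patterned mutant family
#'
#' Builds `n` permutation variants of one synthetic disordered sequence
#' that share the residue composition exactly (hence identical NCPR, fPPII,
#' v_model, and every other composition-based descriptor) while spanning a
#' range of sequence charge decoration: variant 1 alternates the charges
#' (well-mixed, SCD near its maximum for the composition) and successive
#' variants move the charge arrangement stepwise toward full segregation
#' (blocky, strongly negative SCD). The first record is the designated wild
#' type (`id = "WT"`).
#'
#' @param length sequence length (default 150)
#' @param nPos,nNeg numbers of Lys/Arg and Glu/Asp residues (defaults 12/12,
#'   i.e. NCPR = 0)
#' @param n number of variants (>= 2)
#' @param seed RNG seed (controls the neutral background)
#' @return data frame: id, sequence, family
#' @export
makeChargeFamily <- function(length = 150L, nPos = 12L, nNeg = 12L, n = 11L,
                             seed = 1L) {
  stopifnot(n >= 2L, nPos + nNeg <= length)
  .withSeed(seed, {
    neutralProfile <- c(G = 0.20, S = 0.20, N = 0.12, Q = 0.12, T = 0.08,
                        A = 0.10, P = 0.08, Y = 0.06, F = 0.04)
    background <- sample(names(neutralProfile), length - nPos - nNeg,
                         replace = TRUE, prob = neutralProfile)
    pos <- rep(c("K", "R"), length.out = nPos)
    neg <- rep(c("E", "D"), length.out = nNeg)
    # charge sites evenly spread along the chain; variants permute which
    # sign occupies which site
    sites <- round(seq(1L, length, length.out = nPos + nNeg))
    mixed <- rep(c(1L, -1L), length.out = nPos + nNeg)  # alternating
    mixed <- .balanceSigns(mixed, nPos, nNeg)
    blocky <- c(rep(1L, nPos), rep(-1L, nNeg))          # fully segregated
    seqFor <- function(signs) {
      chars <- character(length)
      chars[-sites] <- background
      chars[sites[signs > 0]] <- pos
      chars[sites[signs < 0]] <- neg
      paste(chars, collapse = "")
    }
    # interpolate: swap prefix of the transposition path mixed -> blocky
    path <- .signPath(mixed, blocky)
    steps <- round(seq(0, base::length(path), length.out = n))
    seqs <- vapply(steps, function(k) {
      s <- mixed
      if (k > 0) for (sw in path[seq_len(k)]) {
        tmp <- s[sw[1]]; s[sw[1]] <- s[sw[2]]; s[sw[2]] <- tmp
      }
      seqFor(s)
    }, character(1))
    data.frame(id = c("WT", sprintf("scd%02d", seq_len(n - 1L))),
               sequence = seqs, family = "synthetic",
               stringsAsFactors = FALSE)
  })
}

# force an alternating template to the exact +/- counts
.balanceSigns <- function(signs, nPos, nNeg) {
  excess <- sum(signs > 0) - nPos
  if (excess > 0) signs[utils::tail(which(signs > 0), excess)] <- -1L
  if (excess < 0) signs[utils::tail(which(signs < 0), -excess)] <- 1L
  signs
}

# transposition sequence turning arrangement `from` into `to`
.signPath <- function(from, to) {
  path <- list()
  s <- from
  for (i in seq_along(to)) {
    if (s[i] != to[i]) {
      j <- i + which(s[(i + 1):base::length(s)] == to[i])[1]
      path[[base::length(path) + 1L]] <- c(i, j)
      tmp <- s[i]; s[i] <- s[j]; s[j] <- tmp
    }
  }
  path
}

#' Synthetic saturation-concentration series
#'
#' Generates `c_sat(T) = c_dense * exp((dh - T*ds) / (R*T))` from chosen
#' thermodynamic parameters, optionally perturbed by lognormal noise, so
#' that [vantHoff()] recovery can be tested exactly (zero noise) and
#' statistically (noise > 0).
#'
#' @param dh standard molar enthalpy, kJ/mol
#' @param ds standard molar entropy, kJ/mol/K
#' @param cDense condensed-phase concentration, M
#' @param temperatures Kelvin
#' @param noiseSd SD of the noise on ln(c_sat) (default 0)
#' @param seed RNG seed
#' @return data frame: temperature, csat; generating parameters in
#'   attribute `params`
#' @export
makeCsatSeries <- function(dh, ds, cDense, temperatures,
                           noiseSd = 0, seed = 1L) {
  .withSeed(seed, {
    lnC <- log(cDense) + (dh * 1000 - temperatures * ds * 1000) /
      (.GAS_R * temperatures)
    if (noiseSd > 0) lnC <- lnC + stats::rnorm(base::length(temperatures),
                                               sd = noiseSd)
    out <- data.frame(temperature = temperatures, csat = exp(lnC))
    attr(out, "params") <- list(dh = dh, ds = ds, cDense = cDense,
                                noiseSd = noiseSd)
    out
  })
}
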