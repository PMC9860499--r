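#!/usr/bin/env Rscript
# One-time calibration of the synthetic class composition profiles.
#
# For each class (psid / id / folded) we tilt a literature-style base
# composition exponentially along the beta-turn and -ln(PPII) directions
# (two knobs controlling the set means of beta-turn propensity and v_model),
# with a Dirichlet concentration knob (between-sequence spread) and a
# length-range half-width knob (extra v_model spread at fixed composition),
# and minimize the squared standardized error of the simulated set means
# and SDs of v_model and beta-turn against the class targets:
#   psid:   v 0.542 +/- 0.020, turn 1.152 +/- 0.087
#   id:     v 0.558 +/- 0.022, turn 1.101 +/- 0.075
#   folded: v 0.537 +/- 0.008, turn 0.971 +/- 0.040
# The optimized profiles are frozen into R/fixtures-profiles.R; this script
# is kept for provenance and is not rerun at build or test time.

pkgload::load_all(".", quiet = TRUE)

BASE <- list(
  folded = c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9, E = 6.7,
             G = 7.1, H = 2.3, I = 5.9, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
             P = 4.7, S = 6.6, T = 5.4, W = 1.1, Y = 2.9, V = 6.9),
  id = c(A = 7.5, R = 5.0, N = 4.0, D = 5.5, C = 0.5, Q = 6.0, E = 10.0,
         G = 7.5, H = 1.8, I = 2.5, L = 4.5, K = 8.5, M = 1.5, F = 1.8,
         P = 9.0, S = 9.5, T = 5.5, W = 0.3, Y = 1.6, V = 3.5),
  psid = c(A = 5.5, R = 4.5, N = 7.0, D = 3.5, C = 0.4, Q = 8.5, E = 4.0,
           G = 13.0, H = 1.5, I = 1.8, L = 3.0, K = 4.5, M = 1.8, F = 2.5,
           P = 6.5, S = 12.5, T = 4.5, W = 0.5, Y = 4.5, V = 2.5))

TARGETS <- list(
  psid = c(mv = 0.542, sv = 0.020, mt = 1.152, st = 0.087),
  id = c(mv = 0.558, sv = 0.022, mt = 1.101, st = 0.075),
  folded = c(mv = 0.537, sv = 0.008, mt = 0.971, st = 0.040))

CENTER <- c(psid = 150L, id = 120L, folded = 200L)

turnV <- parse2:::.BETA_TURN_VALUES[AA_STANDARD]
ppiiV <- parse2:::.PPII_VALUES[AA_STANDARD]

tilt <- function(base, l1, l2) {
  p <- base[AA_STANDARD] * exp(l1 * scale(turnV)[, 1] -
                               l2 * scale(log(ppiiV))[, 1])
  p / sum(p)
}

simulate <- function(p, conc, lenHw, center, n = 900L, seed = 99L) {
  set.seed(seed)
  lens <- sample(max(30L, center - lenHw):(center + lenHw), n, replace = TRUE)
  v <- numeric(n); tn <- numeric(n)
  for (i in seq_len(n)) {
    g <- rgamma(20L, shape = p * conc)
    s <- paste(sample(AA_STANDARD, lens[i], replace = TRUE,
                      prob = g / sum(g)), collapse = "")
    v[i] <- vModel(s)
    tn[i] <- sequenceMean(parse2:::.BETA_TURN_VALUES, s)
  }
  c(mv = mean(v), sv = sd(v), mt = mean(tn), st = sd(tn))
}

fitClass <- function(cls) {
  tg <- TARGETS[[cls]]
  obj <- function(par) {
    p <- tilt(BASE[[cls]], par[1], par[2])
    got <- simulate(p, exp(par[3]), max(10, round(exp(par[4]))), CENTER[[cls]])
    # mean errors are weighted at standard-error scale (the set means drive
    # the between-class separations and hence the test p-values); SD errors
    # at 30% relative scale
    sum(((got - tg) / c(tg["sv"] / 12, 0.15 * tg["sv"],
                        tg["st"] / 12, 0.15 * tg["st"]))^2)
  }
  best <- optim(c(0, 0, log(150), log(40)), obj,
                control = list(maxit = 600, reltol = 1e-5))
  p <- tilt(BASE[[cls]], best$par[1], best$par[2])
  conc <- exp(best$par[3])
  hw <- max(10L, round(exp(best$par[4])))
  got <- simulate(p, conc, hw, CENTER[[cls]])
  cat(sprintf("%-7s obj=%.2f  mv=%.4f sv=%.4f mt=%.4f st=%.4f\n",
              cls, best$value, got[1], got[2], got[3], got[4]))
  list(profile = round(p, 6), concentration = round(conc, 2),
       lengthRange = c(max(30L, CENTER[[cls]] - hw), CENTER[[cls]] + hw))
}

res <- lapply(c("psid", "id", "folded"), fitClass)
names(res) <- c("psid", "id", "folded")

fmt <- function(x) paste(sprintf("%s = %.6f", names(x), x), collapse = ", ")
lines <- c(
  "# Frozen composition profiles for the synthetic class generators.",
  "# Produced once by scripts/tune_compositions.R (see that file for the",
  "# calibration targets); do not edit by hand.",
  ".CLASS_PROFILES <- list(")
for (cls in names(res)) {
  r <- res[[cls]]
  lines <- c(lines,
    sprintf("  %s = list(", cls),
    sprintf("    profile = c(%s),", fmt(r$profile)),
    sprintf("    concentration = %.2f,", r$concentration),
    sprintf("    lengthRange = c(%dL, %dL)),", r$lengthRange[1], r$lengthRange[2]))
}
lines[length(lines)] <- sub("\\),$", "))", lines[length(lines)])
writeLines(lines, "R/fixtures-profiles.R")
cat("wrote R/fixtures-profiles.R\n")
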