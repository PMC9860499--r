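test_that("pi-contact potential matches its term-by-term oracle", {
  g23 <- strrep("G", 23)
  expect_equal(uPi(strrep("G", 25)), 0)
  expect_equal(uPi(paste0(g23, "YR")), 3)          # equal-count divisor rule
  expect_equal(uPi(paste0(g23, "YR"), a = 0.5), 1.5)
  # #Y=3, #R=1: 3*(3*1/2) = 4.5
  expect_equal(uPi(paste0(strrep("G", 21), "YYYR")), 4.5)
  set.seed(71)
  for (i in 1:20) {
    w <- randomSeq(25, prob = c(rep(1, 20)) +
                     8 * (AA_STANDARD %in% c("Y", "F", "R", "K", "G")))
    expect_equal(uPi(w, a = 0.37), oracleUPi(w, a = 0.37))
  }
})

test_that("charge potential is b*SCD + c*|NCPR| per window", {
  expect_equal(uQ(strrep("G", 25), b = 5, c = 9), 0)
  w <- paste0(strrep("G", 21), "KKEE")
  expect_equal(uQ(w, b = 0, c = 3), 3 * abs(ncpr(w)))
  expect_equal(uQ(w, b = 2, c = 3), 2 * scd(w) + 3 * abs(ncpr(w)))
  # same composition, different patterning: only the SCD term differs
  w2 <- paste0(strrep("G", 21), "KEKE")
  expect_equal(uQ(w, 2, 3) - uQ(w2, 2, 3), 2 * (oracleSCD(w) - oracleSCD(w2)))
})

test_that("applying zero potentials is the identity", {
  cl <- classifyWindows(makeBlockCopolymer(
    list(list(composition = "ps", length = 50),
         list(composition = "id", length = 50)), seed = 4))
  cl0 <- applyPotentials(cl, 0, 0, 0)
  expect_identical(windows(cl)$label, windows(cl0)$label)
  expect_equal(windows(cl)$distance, windows(cl0)$distance)
  expect_equal(summedPDistance(cl), summedPDistance(cl0))
})

test_that("D windows flip to P when the correction exceeds their distance", {
  # an ID-like window with one Y, one R and no F/K: u_pi = 3a exactly
  w <- paste0(strrep("E", 10), strrep("D", 9), strrep("A", 4), "YR")
  expect_equal(nchar(w), 25)
  s <- paste0(w, "E")                       # N = 26: two near-identical windows
  cl <- classifyWindows(s)
  expect_true(all(windows(cl)$label == "D"))
  d0 <- windows(cl)$distance[1]
  aFlip <- (d0 + 0.2) / 3                   # makes U = d0 + 0.2 at window 1
  corrected <- applyPotentials(cl, a = aFlip)
  expect_equal(windows(corrected)$label[1], "P")
  expect_equal(windows(corrected)$distance[1], 0.2, tolerance = 1e-9)
  # below the threshold no flip happens
  weak <- applyPotentials(cl, a = d0 / 3 * 0.99)
  expect_equal(windows(weak)$label[1], "D")
})

test_that("the corrected summed potential is nondecreasing in a and in c", {
  s <- makeBlockCopolymer(list(list(composition = "ps", length = 60),
                               list(composition = "id", length = 60)),
                          seed = 9)
  cl <- classifyWindows(s)
  pots <- vapply(seq(0, 1, by = 0.1), function(a)
    summedPDistance(applyPotentials(cl, a = a)), numeric(1))
  expect_true(all(diff(pots) >= -1e-9))
  potsC <- vapply(seq(0, 20, by = 2), function(cc)
    summedPDistance(applyPotentials(cl, c = cc)), numeric(1))
  expect_true(all(diff(potsC) >= -1e-9))
})

test_that("van't Hoff analysis recovers generating thermodynamics", {
  # noiseless series: exact recovery and the dg identity to machine precision
  ser <- makeCsatSeries(dh = -65, ds = -0.21, cDense = 0.03,
                        temperatures = seq(276, 330, by = 6))
  th <- vantHoff(ser$temperature, ser$csat, 0.03)
  expect_equal(th$dh, -65, tolerance = 1e-10)
  expect_equal(th$ds, -0.21, tolerance = 1e-10)
  expect_equal(th$dg, th$dh - 273.15 * th$ds)
  expect_lt(th$residual, 1e-12)

  # two points: the fit interpolates exactly
  ser2 <- makeCsatSeries(-40, -0.1, 0.01, c(280, 300))
  th2 <- vantHoff(ser2$temperature, ser2$csat, 0.01)
  expect_equal(th2$dh, -40, tolerance = 1e-10)

  # noisy series: unbiased recovery over replicates
  reps <- vapply(1:120, function(i) {
    s <- makeCsatSeries(-65, -0.21, 0.03, seq(276, 330, by = 6),
                        noiseSd = 0.08, seed = i)
    vantHoff(s$temperature, s$csat, 0.03)$dh
  }, numeric(1))
  expect_equal(mean(reps), -65, tolerance = 0.02 * 65)

  expect_error(vantHoff(300, 0.01, 0.03), "two distinct")
  expect_error(vantHoff(c(300, 310), c(-1, 0.01), 0.03), "positive")
})

test_that("fitA recovers a forward-simulated coefficient", {
  fam <- makeChargeFamily(n = 9, seed = 5)
  # add aromatic/cationic variation at fixed charge pattern by swapping
  # neutral residues for Y/F in different windows
  fam$sequence <- vapply(seq_len(nrow(fam)), function(i) {
    s <- strsplit(fam$sequence[i], "")[[1]]
    neutral <- which(s %in% c("G", "S", "N", "Q", "T", "A"))
    set.seed(100 + i)
    s[sample(neutral, min(2 * i, 14))] <- "Y"
    paste(s, collapse = "")
  }, character(1))
  truth <- vapply(fam$sequence, psPotential, numeric(1), a = 0.2,
                  USE.NAMES = FALSE)
  set.seed(55)
  fam$dh <- -(truth + rnorm(nrow(fam), sd = 0.01 * sd(truth))) # affine + noise
  fit <- fitA(fam, "dh", grid = seq(0, 1, by = 0.01))
  expect_lt(abs(fit$a - 0.2), 0.06)
  expect_gt(abs(fit$r), 0.98)

  # observable orthogonalized against the potential manifold: correlation
  # stays near zero for every a, which is flagged
  pots <- vapply(c(0, 0.3, 0.6, 1), function(a)
    vapply(fam$sequence, psPotential, numeric(1), a = a, USE.NAMES = FALSE),
    numeric(nrow(fam)))
  set.seed(56)
  fam$dh <- unname(resid(lm(rnorm(nrow(fam)) ~ pots)))
  expect_warning(fitA(fam, "dh"), "weak correlation")
  # degenerate observable rejected
  fam$dh <- rep(1, nrow(fam))
  expect_error(fitA(fam, "dh"), "constant")
})

test_that("fitBC recovers forward-simulated charge coefficients", {
  fam <- makeChargeFamily(n = 10, nPos = 14, nNeg = 10, seed = 6)
  truth <- vapply(fam$sequence, psPotential, numeric(1), a = 0, b = 6, c = 4,
                  USE.NAMES = FALSE)
  set.seed(66)
  fam$dh <- -(truth + rnorm(nrow(fam), sd = 0.005 * sd(truth)))
  fit <- fitBC(fam, "dh", a = 0, bGrid = seq(0, 10, by = 0.5),
               cGrid = seq(0, 10, by = 0.5))
  expect_lt(abs(fit$b - 6), 1)
  expect_gt(abs(fit$r), 0.98)
  # with b = c = 0 ground truth the U_q term cannot improve the correlation
  fam$dh <- -vapply(fam$sequence, psPotential, numeric(1), USE.NAMES = FALSE)
  fit0 <- fitBC(fam, "dh", a = 0, bGrid = seq(-2, 2, by = 1),
                cGrid = seq(-2, 2, by = 1), refine = 0)
  expect_gte(abs(fit0$r), 0.999)
})

test_that("directional agreement handles perfect and degenerate families", {
  fam <- makeChargeFamily(n = 8, nPos = 14, nNeg = 10, seed = 7)
  pot <- vapply(fam$sequence, psPotential, numeric(1), b = 6, c = 4,
                USE.NAMES = FALSE)
  fam$dh <- -pot                         # perfectly anti-correlated = agree
  da <- directionalAgreement(fam, "dh", b = 6, c = 4)
  expect_equal(da$fraction, 1)
  # mutants identical to WT are excluded from the denominator
  fam2 <- fam
  fam2$sequence <- rep(fam$sequence[1], nrow(fam))
  fam2$dh <- rep(fam$dh[1], nrow(fam))
  da2 <- directionalAgreement(fam2, "dh", b = 6, c = 4)
  expect_true(is.na(da2$fraction))
  expect_equal(da2$excluded, nrow(fam) - 1)
})

test_that("mutant tables round-trip with wide c_sat columns", {
  df <- data.frame(id = c("WT", "m1"), sequence = c(strrep("GS", 20),
                                                    strrep("GN", 20)),
                   family = "A1-LCD", dh = c(-60, -50),
                   `csat@290` = c(1e-4, 2e-4), `csat@310` = c(5e-4, NA),
                   check.names = FALSE)
  tmp <- tempfile(fileext = ".tsv")
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  mt <- readMutantTable(tmp)
  expect_equal(mt$table$id, c("WT", "m1"))
  expect_equal(nrow(mt$csat), 3)           # the NA point is dropped
  expect_equal(sort(unique(mt$csat$temperature)), c(290, 310))
})

test_that("charge-matched filtering keeps only WT-like variants", {
  # variants that permute neutral residues only: charges stay in place, so
  # NCPR and SCD match the wild type exactly
  wt <- makeChargeFamily(n = 2, seed = 8)$sequence[1]
  chars <- strsplit(wt, "")[[1]]
  neutral <- which(!chars %in% c("K", "R", "E", "D"))
  set.seed(81)
  fam <- data.frame(id = c("WT", paste0("perm", 1:4)), sequence = vapply(0:4,
    function(i) {
      s <- chars
      if (i > 0) s[neutral] <- s[sample(neutral)]
      paste(s, collapse = "")
    }, character(1)), stringsAsFactors = FALSE)
  expect_equal(nrow(filterChargeMatched(fam)), nrow(fam))
  # moving a charge breaks the SCD match; changing the charge count
  # breaks the NCPR match
  s3 <- strsplit(fam$sequence[3], "")[[1]]
  c1 <- which(s3 %in% c("K", "R"))[1]
  n1 <- utils::tail(which(!s3 %in% c("K", "R", "E", "D")), 1)
  tmp <- s3[c1]; s3[c1] <- s3[n1]; s3[n1] <- tmp
  stopifnot(abs(scd(paste(s3, collapse = "")) -
                  scd(fam$sequence[1])) > 1e-9)
  fam$sequence[3] <- paste(s3, collapse = "")
  fam$sequence[4] <- paste0(substr(fam$sequence[4], 1, 140), strrep("K", 10))
  kept <- filterChargeMatched(fam)
  expect_equal(nrow(kept), nrow(fam) - 2)
  expect_false(any(kept$id %in% c("perm2", "perm3")))
})
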