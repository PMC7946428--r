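test_that("knock-in efficiency is the GFP+/denominator+ percentage", {
  expect_equal(round(kiEfficiency(14, 36)$percent, 1), 38.9)
  expect_equal(kiEfficiency(0, 25)$percent, 0)
  expect_error(kiEfficiency(3, 0), "denominator")

  # per-coverslip averaging: mean of per-coverslip percentages, SEM over
  # coverslips (hand-computed for a 3-coverslip fixture)
  eff <- kiEfficiency(c(10, 20, 15), c(40, 50, 60))
  byHand <- c(25, 40, 25)
  expect_equal(eff$perCoverslip, byHand)
  expect_equal(eff$mean, mean(byHand))
  expect_equal(eff$sem, sd(byHand) / sqrt(3))
})

test_that("KI/WT/KO classification splits on the maxiROI threshold", {
  rec <- data.frame(mcherryPos = TRUE, gfpPos = c(FALSE, FALSE),
                    markerIntensity = c(300, 10))
  got <- classifyKiWtKo(rec, maxiroiIntensity = 50)
  expect_equal(unname(got$counts), c(0L, 1L, 1L))

  allKi <- data.frame(mcherryPos = TRUE, gfpPos = TRUE,
                      markerIntensity = runif(10, 0, 500))
  expect_equal(unname(classifyKiWtKo(allKi, 50)$fractions["KI"]), 1)

  # partition: KI + WT + KO fractions always sum to 1 over mCherry+ cells
  ct <- makeCellTable(400, pKi = 0.3, pKo = 0.2, seed = 5)
  got <- classifyKiWtKo(ct$cells, maxiroiIntensity = 60)
  expect_equal(sum(got$fractions), 1)
  expect_equal(sum(got$counts), 400L)
})

test_that("synthetic cohorts are recovered within binomial error", {
  n <- 10000L
  ct <- makeCellTable(n, pKi = 0.389, pKo = 0.124, seed = 11)
  got <- classifyKiWtKo(ct$cells, maxiroiIntensity = 60)
  se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(got$fractions[["KI"]] - 0.389), 3 * se(0.389))
  expect_lt(abs(got$fractions[["KO"]] - 0.124), 3 * se(0.124))
})

test_that("colocalization slope equals closed-form OLS", {
  got <- colocSlope(c(1, 2, 3), c(2, 4, 6))
  expect_equal(got$slope, 2.0)
  expect_equal(got$r2, 1.0)

  # closed-form check on a random fixture
  set.seed(4)
  a <- runif(50); b <- 3 * a + rnorm(50, sd = 0.2)
  got <- colocSlope(a, b)
  expect_equal(got$slope, cov(a, b) / var(a))
  expect_equal(got$intercept, mean(b) - got$slope * mean(a))

  # statistical null: uncorrelated noise gives slope ~ 0 within 3 SE
  set.seed(7)
  a <- rnorm(1000); b <- rnorm(1000)
  fit <- summary(lm(b ~ a))
  expect_lt(abs(colocSlope(a, b)$slope), 3 * fit$coefficients[2, 2])

  # generated slope 0.8 recovered within +/- 0.05 at n = 800, sd = 0.1
  set.seed(9)
  a <- runif(800, 0, 2); b <- 0.8 * a + rnorm(800, sd = 0.1)
  expect_lt(abs(colocSlope(a, b)$slope - 0.8), 0.05)

  expect_error(colocSlope(rep(1, 5), 1:5), "degenerate")
})

test_that("FRAP normalization sets pre-bleach to 1 and bleach point to 0", {
  t <- 0:11
  raw <- c(100, 100, 0, 40, 60, 70, 75, 78, 80, 80, 80, 80)
  tr <- normalizeFrap(t, raw, rep(0, 12), rep(0, 12), bleachIndex = 3)
  expect_equal(mean(tr@f[1:2]), 1)
  expect_equal(tr@f[3], 0)

  # adding a constant to signal and both backgrounds changes nothing
  tr2 <- normalizeFrap(t, raw + 50, rep(50, 12), rep(50, 12), 3)
  expect_equal(tr2@f, tr@f)

  # an already-normalized trace passes through unchanged
  tr3 <- normalizeFrap(t, tr@f, rep(0, 12), rep(0, 12), 3)
  expect_equal(tr3@f, tr@f)

  expect_error(normalizeFrap(t, rep(1, 12), rep(2, 12), rep(2, 12), 3),
               "trace unusable")
})

test_that("one-phase-decay fit recovers generating parameters exactly", {
  # generator self-check at the closed-form point f(tau) = plateau(1 - 1/e)
  expect_equal(round(0.4756 * (1 - exp(-1)), 4), 0.3006)

  tr <- makeFrapTrace(tau = 3.057, immobileFrac = 0.5244, noiseSd = 0)
  fit <- fitFrap(tr)
  expect_equal(frapTau(fit), 3.057, tolerance = 1e-6)
  expect_equal(100 * immobileFrac(fit), 52.44, tolerance = 1e-4)
  expect_lt(fit@residualRMS, 1e-8)

  # full recovery limit: plateau 1 -> immobile fraction 0
  full <- fitFrap(makeFrapTrace(tau = 2, immobileFrac = 0, noiseSd = 0))
  expect_equal(immobileFrac(full), 0, tolerance = 1e-6)

  # no recovery: flat zeros -> immobile fraction 1
  none <- fitFrap(makeFrapTrace(tau = 2, immobileFrac = 1, noiseSd = 0))
  expect_equal(immobileFrac(none), 1)
})

test_that("FRAP fit is scale-consistent in time", {
  tr1 <- makeFrapTrace(tau = 3, immobileFrac = 0.4, noiseSd = 0, dt = 1)
  f1 <- fitFrap(tr1)
  # stretching the clock by c scales the fitted time constant by c
  f2 <- fitFrap(FrapTrace(tr1@t * 2, tr1@f, 3L))
  expect_equal(frapTau(f2), 2 * frapTau(f1), tolerance = 1e-6)
  # a trace sampled at a different dt from the same tau still returns tau
  tr2 <- makeFrapTrace(tau = 3, immobileFrac = 0.4, noiseSd = 0, dt = 2)
  expect_equal(frapTau(fitFrap(tr2)), 3, tolerance = 1e-6)
})

test_that("parameter recovery holds over noisy seeded traces", {
  # 20 post-bleach points at sigma = 0.02: tau is only weakly identified
  # from very short noisy traces, which is why pooling across spines is the
  # analysis convention
  tauErr <- immErr <- numeric(100)
  for (i in 1:100) {
    tr <- makeFrapTrace(tau = 3, immobileFrac = 0.48, noiseSd = 0.02,
                        nPost = 20, seed = i)
    fit <- fitFrap(tr)
    tauErr[i] <- abs(frapTau(fit) - 3) / 3
    immErr[i] <- abs(immobileFrac(fit) - 0.48)
  }
  expect_lte(median(tauErr), 0.05)
  expect_lte(median(immErr), 0.02)
})

test_that("pooled FRAP fits the pointwise mean trace", {
  tr <- makeFrapTrace(tau = 3, immobileFrac = 0.5, noiseSd = 0)
  same <- poolFrap(replicate(46, tr, simplify = FALSE))
  expect_equal(frapTau(same$fit), frapTau(fitFrap(tr)), tolerance = 1e-8)
  expect_true(all(same$sem == 0))

  # plateau mixes linearly at fixed tau: {0.4, 0.6} pools to 0.5
  a <- makeFrapTrace(tau = 3, immobileFrac = 0.6, noiseSd = 0)
  b <- makeFrapTrace(tau = 3, immobileFrac = 0.4, noiseSd = 0)
  mixed <- poolFrap(list(a, b))
  expect_equal(mixed$fit@plateau, 0.5, tolerance = 1e-6)
  expect_equal(frapTau(mixed$fit), 3, tolerance = 1e-6)

  # 46 noisy spines pool to within 5% of the generating parameters
  traces <- lapply(1:46, function(i)
    makeFrapTrace(tau = 3, immobileFrac = 0.52, noiseSd = 0.05, seed = i))
  pooled <- poolFrap(traces)
  expect_lt(abs(frapTau(pooled$fit) - 3) / 3, 0.05)
  expect_lt(abs(immobileFrac(pooled$fit) - 0.52) / 0.52, 0.05)

  short <- makeFrapTrace(tau = 3, immobileFrac = 0.5, noiseSd = 0, nPost = 6)
  expect_error(poolFrap(list(tr, short)), "grid mismatch")
})
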