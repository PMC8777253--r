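# Build a deterministic FrequencyTrace on the standard 13 s / 25 ms grid
# from a rate function evaluated at bin centers (noise-free traces for
# exact-decomposition checks).
kernelTrace <- function(rateFun, stage = "raw", labels = list(sensillum = "ab1")) {
  k <- seq(-120, 399)
  centers <- (k + 0.5) * 0.025
  new("FrequencyTrace", times = centers, rate = rateFun(centers),
      binWidth = 0.025, stage = stage, labels = labels)
}

test_that("gust-mean subtraction is exact, linear, and stage-checked", {
  mech <- function(t) 50 * alphaKernel(t, 0.05)
  odor <- function(t) 120 * alphaKernel(t, 0.1)

  gust <- kernelTrace(mech)
  both <- kernelTrace(function(t) odor(t) + mech(t))

  gm <- meanGustTrace(list(gust, gust))
  expect_equal(binRate(gm), binRate(gust))

  # subtracting the gust mean from itself gives an all-zero trace
  zero <- gustCorrect(gust, gm)
  expect_true(all(abs(binRate(zero)) < 1e-12))
  expect_equal(traceStage(zero), "gust_corrected")

  # zero gust mean is the identity
  gz <- kernelTrace(function(t) 0 * t)
  expect_equal(binRate(gustCorrect(both, gz)), binRate(both))

  # noise-free decomposition: (odor + mech) - mech = odor, bin-exactly
  resid <- gustCorrect(both, gm)
  expect_equal(binRate(resid), odor(binTimes(both)), tolerance = 1e-12)

  # corrected values may go negative; no clipping
  dip <- gustCorrect(kernelTrace(function(t) 0 * t), gm)
  expect_lt(min(binRate(dip)), 0)

  short <- new("FrequencyTrace", times = c(0, 0.025), rate = c(1, 1),
               binWidth = 0.025, stage = "raw", labels = list())
  expect_error(gustCorrect(short, gm), "grid")
  expect_error(gustCorrect(zero, gm), "raw")
  expect_error(meanGustTrace(list()), "no air-gust")
  expect_error(meanGustTrace(list(
    kernelTrace(mech, labels = list(sensillum = "ab1")),
    kernelTrace(mech, labels = list(sensillum = "ab2")))), "sensilla")
})

test_that("rolling-average smoothing matches the sliding-window oracle", {
  withr::local_seed(71)
  tr <- kernelTrace(function(t) pmax(0, rnorm(length(t), 20, 8)))
  sm <- smoothTrace(tr)                      # default 400 ms = 16 bins
  expect_equal(binRate(sm), slidingMean(binRate(tr), 16))
  expect_equal(binTimes(sm), slidingMean(binTimes(tr), 16))
  expect_equal(length(binRate(sm)), length(binRate(tr)) - 15L)
  expect_equal(traceStage(sm), "smoothed")

  # constant traces stay constant; the max never grows
  const <- kernelTrace(function(t) rep(7, length(t)))
  expect_true(all(binRate(smoothTrace(const)) == 7))
  expect_lte(max(binRate(sm)), max(binRate(tr)))

  # a window of one bin is the identity
  one <- smoothTrace(tr, window = 0.025)
  expect_equal(binRate(one), binRate(tr))

  expect_error(smoothTrace(tr, window = 0.41), "multiple")
  tiny <- new("FrequencyTrace", times = c(0, 0.025), rate = c(1, 2),
              binWidth = 0.025, stage = "raw", labels = list())
  expect_error(smoothTrace(tiny, window = 0.4), "longer")
})

test_that("peak and AUC extraction respects stage-dependent windows", {
  # symmetric triangle: height 40 sp/s, base 0.5 s => area 1/2 * 0.5 * 40 = 10;
  # apex and feet on bin centers, so the sampled trace is piecewise linear
  # between its nodes and the trapezoid rule is exact
  tri <- function(t) pmax(0, 40 * (1 - abs(t - 0.3625) / 0.25))
  tr <- kernelTrace(tri)
  m <- extractMetrics(tr)
  expect_equal(m$peak, 40)
  expect_equal(m$auc, 10, tolerance = 1e-9)
  expect_equal(c(m$windowStart, m$windowEnd), c(0, 1))

  # trapezoid equals a 100x-refined Riemann sum on random traces
  withr::local_seed(81)
  for (i in 1:20) {
    rnd <- kernelTrace(function(t) pmax(0, rnorm(length(t), 10, 5)))
    got <- extractMetrics(rnd)$auc
    inWin <- binTimes(rnd) >= -1e-9 & binTimes(rnd) <= 1 + 1e-9
    want <- refinedRiemann(binTimes(rnd)[inWin], binRate(rnd)[inWin])
    expect_equal(got, want, tolerance = 1e-9)
  }

  # all-zero trace: both metrics zero
  z <- extractMetrics(kernelTrace(function(t) 0 * t))
  expect_equal(c(z$peak, z$auc), c(0, 0))

  # smoothed traces use the widened window starting 0.5 s before onset
  early <- function(t) pmax(0, 40 * (1 - abs(t + 0.3) / 0.1))
  sm <- kernelTrace(early, stage = "smoothed")
  expect_gt(extractMetrics(sm)$peak, 30)     # caught by [-0.5, 1]
  raw <- kernelTrace(early, stage = "raw")
  expect_equal(extractMetrics(raw)$peak, 0)  # invisible in [0, 1]

  cfgNarrow <- analysisConfig(responseWindowRaw = c(5, 6))
  expect_equal(extractMetrics(tr, cfgNarrow)$peak, 0)
})

test_that("the three-step workflow cancels pure mechanical responses", {
  # 16-treatment design, zero odor gains: every response is mechanical, so
  # gust correction should leave only baseline fluctuations
  p <- spikeSimParams(odorGain = 0)
  des <- defaultDesign(nFlies = 6, sensilla = "ab1")
  trains <- simulateCohort(des, p, seed = 21)
  met <- runThreeStep(trains)
  expect_setequal(unique(met$stage), c("raw", "gust_corrected", "smoothed"))
  expect_equal(nrow(met), 3L * length(trains))

  # mean corrected AUC across stimulus trains is statistically zero; the
  # gust mean is shared across a cohort's corrections, so the standard error
  # must include its own sampling variance
  for (coh in c("control", "heatshock")) {
    sel <- met$cohort == coh
    corr <- met$auc[sel & met$stage == "gust_corrected" &
                      !met$treatment %in% c("no treatment", "air gust")]
    rawOdor <- met$auc[sel & met$stage == "raw" &
                         !met$treatment %in% c("no treatment", "air gust")]
    rawGust <- met$auc[sel & met$stage == "raw" & met$treatment == "air gust"]
    se <- sqrt(var(rawOdor) / length(rawOdor) + var(rawGust) / length(rawGust))
    expect_lt(abs(mean(corr)), 3 * se)
  }

  # with an odor component, the corrected stage recovers it (cohort mean)
  p2 <- spikeSimParams()
  trains2 <- simulateCohort(defaultDesign(nFlies = 9, sensilla = "ab2",
                                          cohorts = "control"), p2, seed = 22)
  gusts <- Filter(function(x) x@treatment == "air gust", trains2)
  diag <- Filter(function(x) x@treatment == "methyl acetate", trains2)
  gm <- meanGustTrace(lapply(gusts, frequencyTrace))
  corrected <- lapply(diag, function(x) gustCorrect(frequencyTrace(x), gm))
  mc <- meanTrace(corrected)$trace
  sm <- smoothTrace(mc)
  # noiseless reference: the smoothed binned odor kernel
  ref <- smoothTrace(kernelTrace(function(t) 120 * alphaKernel(t, 0.1),
                                 labels = list(sensillum = "ab2")))
  refPeak <- extractMetrics(ref)$peak
  expect_lt(abs(extractMetrics(sm)$peak - refPeak) / refPeak, 0.2)

  expect_error(runThreeStep(trains2[1:3]), "no 'air gust'")
})

test_that("delta summaries subtract cohort means and flag absent cells", {
  p <- spikeSimParams()
  des <- defaultDesign(nFlies = 5, sensilla = "ab3")
  met <- runThreeStep(simulateCohort(des, p, seed = 23))

  ds <- deltaSummary(met, stage = "raw")
  expect_equal(nrow(ds), 16L)
  expect_true(all(ds$nHeatshock == 5 & ds$nControl == 5))
  # gained mechanosensitivity shows as a positive raw-stage gust delta
  expect_gt(ds$deltaPeak[ds$treatment == "air gust"], 0)

  # identical cohorts: all deltas zero
  half <- met[met$cohort == "control", ]
  dup <- rbind(half, transform(half, cohort = "heatshock"))
  expect_true(all(abs(deltaSummary(dup, stage = "raw")$deltaPeak) < 1e-12))

  # a cell with one cohort is marked absent, not zero
  onlyCtl <- met[met$cohort == "control", ]
  dsa <- deltaSummary(onlyCtl, stage = "smoothed")
  expect_true(all(is.na(dsa$deltaPeak)))
  expect_true(all(dsa$absent == "heatshock"))
})
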