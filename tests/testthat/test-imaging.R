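test_that("dF/F0 matches hand arithmetic and is zero for constant signal", {
  # constant ROI and background: dff identically zero
  m <- cbind(bg = rep(2, 12), roi1 = rep(10, 12))
  rec <- imagingRecording(m, frameInterval = 5,
                          events = stimulusEvents("VUAA1", 55, 0, "odor"))
  d <- computeDff(rec, f0Window = 1:10)
  expect_true(all(abs(dffMatrix(d)) < 1e-12))
  expect_equal(unname(f0Values(d)), 8)

  # step fixture: (12 - 2 - 8) / 8 * 100 = 25 percent
  m2 <- cbind(bg = rep(2, 12), roi1 = c(rep(10, 10), 12, 12))
  rec2 <- imagingRecording(m2, frameInterval = 5,
                           events = stimulusEvents("VUAA1", 50, 0, "odor"))
  d2 <- computeDff(rec2, f0Window = 1:10)
  expect_equal(unname(dffMatrix(d2)[11:12, 1]), c(25, 25))

  # scaling every ROI (cells and background) by 3 leaves dff unchanged
  rec3 <- imagingRecording(3 * m2, frameInterval = 5,
                           events = stimulusEvents("VUAA1", 50, 0, "odor"))
  expect_equal(dffMatrix(computeDff(rec3, 1:10)), dffMatrix(d2))
})

test_that("dF/F0 is invariant to common offsets and scalings", {
  withr::local_seed(31)
  for (i in 1:60) {
    nF <- 30L
    m <- cbind(bg = runif(nF, 1, 3),
               roi1 = runif(nF, 20, 30), roi2 = runif(nF, 40, 50))
    ev <- stimulusEvents("VUAA1", 60, 0, "odor")
    rec <- imagingRecording(m, frameInterval = 5, events = ev)
    d0 <- dffMatrix(computeDff(rec, 1:10))
    shift <- runif(1, 0.5, 20)
    scale <- runif(1, 0.2, 5)
    dShift <- dffMatrix(computeDff(
      imagingRecording(m + shift, frameInterval = 5, events = ev), 1:10))
    dScale <- dffMatrix(computeDff(
      imagingRecording(m * scale, frameInterval = 5, events = ev), 1:10))
    expect_equal(dShift, d0, tolerance = 1e-9)
    expect_equal(dScale, d0, tolerance = 1e-9)
    # normalization conservation: baseline-window mean is 0 per ROI
    expect_true(all(abs(colMeans(d0[1:10, ])) < 1e-9))
  }
})

test_that("dF/F0 guards its preconditions", {
  m <- cbind(bg = rep(10, 12), roi1 = rep(2, 12))  # F0 = -8
  rec <- imagingRecording(m, frameInterval = 5,
                          events = stimulusEvents("VUAA1", 55, 0, "odor"))
  expect_error(computeDff(rec, 1:10), "degenerate baseline.*roi1")

  m2 <- cbind(bg = rep(2, 12), roi1 = rep(10, 12))
  rec2 <- imagingRecording(m2, frameInterval = 5,
                           events = stimulusEvents("VUAA1", 20, 0, "odor"))
  expect_error(computeDff(rec2, 1:10), "overlaps")
})

test_that("responder classification formalizes the by-eye call", {
  # noise-free flat traces are non-responders even with zero baseline SD
  p <- imagingSimParams(3, noiseSd = 0, transientAmplitude = 0)
  d <- computeDff(simulateImagingRecording(p, seed = 1)$recording)
  cl <- classifyResponders(d)
  expect_true(all(cl$label == "non_responder"))
  expect_true(all(cl$score == 0))

  # noise-free transient: zero SD with signal flags an infinite score
  p2 <- imagingSimParams(2, noiseSd = 0, transientAmplitude = 30,
                         responderFraction = 1)
  d2 <- computeDff(simulateImagingRecording(p2, seed = 1)$recording)
  cl2 <- classifyResponders(d2, sdMode = "per_roi")
  expect_true(all(cl2$label == "responder"))
  expect_true(all(is.infinite(cl2$score)))

  # amplitude 30% over ~2.8% baseline noise scores around 10 SDs
  sim <- makeImagingSim(100, "tormogen_ca", seed = 17)
  d3 <- computeDff(sim$recording)
  cl3 <- classifyResponders(d3)
  expect_identical(cl3$label == "responder", sim$truth$responder)
  expect_gt(min(cl3$score[sim$truth$responder]), 5)

  # signed variant: an efflux preset only responds with the matching sign
  simK <- makeImagingSim(50, "osn_k", seed = 19)
  dK <- computeDff(simK$recording)
  up <- classifyResponders(dK, expectedSign = +1)
  down <- classifyResponders(dK, expectedSign = -1)
  expect_true(all(up$label == "non_responder"))
  expect_true(all(down$label == "responder"))
})

test_that("replicate aggregation computes mean and SEM per frame", {
  agg <- aggregateTraces(cbind(c(0, 2), c(2, 4)))
  expect_equal(agg$mean, c(1, 3))
  expect_equal(agg$sem, c(1, 1))  # SD(0,2) = sqrt(2); sqrt(2)/sqrt(2) = 1
  expect_equal(attr(agg, "n"), 2L)

  same <- aggregateTraces(cbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$sem, c(0, 0, 0))

  single <- aggregateTraces(matrix(c(5, 6), ncol = 1), "per_cell")
  expect_equal(single$mean, c(5, 6))
  expect_true(all(is.na(single$sem)))

  expect_error(aggregateTraces(list(c(1, 2), c(1, 2, 3))), "same length")
})

test_that("the extremum time is the argmax of the |mean| envelope", {
  tt <- seq(0, 895, by = 5)
  mk <- function(vals) {
    a <- data.frame(time = tt, mean = vals, sem = 0)
    a
  }
  # one condition peaks at +40 s (10%), the other dips at +60 s (-25%)
  onset <- 300
  v1 <- numeric(length(tt)); v1[tt == onset + 40] <- 10
  v2 <- numeric(length(tt)); v2[tt == onset + 60] <- -25
  expect_equal(findExtremumTime(list(a = mk(v1), b = mk(v2)),
                                c(onset, 895)), onset + 60)

  # all-flat conditions tie-break to the earliest frame of the window
  expect_equal(findExtremumTime(list(a = mk(numeric(length(tt)))),
                                c(onset, 895)), onset)

  # property: equals a brute-force scan on random inputs
  withr::local_seed(41)
  for (i in 1:50) {
    conds <- lapply(1:3, function(j) mk(rnorm(length(tt))))
    got <- findExtremumTime(conds, c(100, 800))
    env <- apply(sapply(conds, function(a) abs(a$mean)), 1, max)
    keep <- tt >= 100 & tt <= 800
    expect_equal(got, tt[keep][which.max(env[keep])])
  }

  expect_error(findExtremumTime(list(a = mk(v1)), c(2000, 3000)), "empty")
})

test_that("dose-response extraction reads fixed frames and mirrors presets", {
  concs <- c(1, 3, 10, 100, 150)
  # replicate recordings per concentration: background-ROI noise is shared
  # within a recording, so only replicates average it out of the mean
  makeCurve <- function(preset, amp0, base) {
    recs <- lapply(concs, function(cc) {
      lapply(1:8, function(r) {
        amp <- concentrationAmplitude(cc, amp0)
        p <- imagingSimParams(6, preset, transientAmplitude = amp,
                              responderFraction = 1, noiseSd = 0.2)
        computeDff(simulateImagingRecording(
          p, seed = base + 10 * cc + r)$recording)
      })
    })
    names(recs) <- concs
    recs
  }
  the <- makeCurve("thecogen_k", +8, 1000)
  osn <- makeCurve("osn_k", -20, 5000)
  evalTime <- 300 + 85
  cThe <- doseResponse(the, evalTime)
  cOsn <- doseResponse(osn, evalTime)
  expect_true(all(diff(cThe$mean) < 0))   # positive, strictly decreasing
  expect_true(all(cThe$mean > 0))
  expect_true(all(diff(cOsn$mean) > 0))   # negative, rising toward zero
  expect_true(all(cOsn$mean < 0))

  # all-zero traces give all-zero points
  zero <- lapply(concs, function(cc) {
    p <- imagingSimParams(3, noiseSd = 0, transientAmplitude = 0)
    computeDff(simulateImagingRecording(p, seed = 1)$recording)
  })
  names(zero) <- concs
  cz <- doseResponse(zero, evalTime)
  expect_true(all(abs(cz$mean) < 1e-12))

  expect_error(doseResponse(the, 301.7), "interpolation refused")
})
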