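#' Count spikes in a half-open window
#'
#' Counts spike times t with a <= t < b. All counting windows in the package
#' are half-open so adjacent windows never double-count a spike.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param window numeric(2), seconds, a < b, within the recording span.
#' @return integer count.
#' @examples
#' countSpikes(spikeTrain(c(0.1, 0.5, 1.0)), c(0, 1))  # 2
#' @export
countSpikes <- function(train, window) {
  stopifnot(is(train, "SpikeTrain"), length(window) == 2L)
  if (window[1] >= window[2]) stop("window must satisfy a < b")
  if (window[1] < -1e-9 || window[2] > train@span + 1e-9) {
    stop("window exceeds the recording span")
  }
  sum(train@spikeTimes >= window[1] & train@spikeTimes < window[2])
}

#' Stimulus response magnitude (delta spikes)
#'
#' The profile statistic: spikes in the 1 s following stimulus onset minus
#' spikes in the 1 s preceding it (both windows half-open).
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @return integer, post minus pre count.
#' @export
responseMagnitude <- function(train) {
  on <- train@stimulusOnset
  if (on - 1 < -1e-9 || on + 1 > train@span + 1e-9) {
    stop("stimulus onset +/- 1 s exceeds the recording span")
  }
  countSpikes(train, c(on, on + 1)) - countSpikes(train, c(on - 1, on))
}

#' Resting activity from a full "no treatment" recording
#'
#' Total spike count over the 13 s stimulus-free recording divided by 13.
#'
#' @param train a \linkS4class{SpikeTrain} with treatment "no treatment" and
#'   a 13 s span.
#' @return list of class \code{RestingActivity}: \code{method}, \code{rate}
#'   (spikes/s) and \code{components} (the raw count).
#' @export
restingActivityNoTreatment <- function(train) {
  stopifnot(is(train, "SpikeTrain"))
  if (train@treatment != "no treatment") {
    stop("resting activity over the full span requires a 'no treatment' recording")
  }
  if (abs(train@span - 13) > 1e-9) {
    stop("the full-span estimator is defined for 13 s recordings")
  }
  n <- nSpikes(train)
  structure(list(method = "no_treatment_13s", rate = n / 13,
                 components = c(count = n, seconds = 13)),
            class = "RestingActivity")
}

#' Resting activity from pre-stimulus windows across the panel
#'
#' Sums the spikes in the 1 s window before stimulus onset across all 16
#' treatments of one fly/neuron and divides by 16.
#'
#' @param trains list of 16 \linkS4class{SpikeTrain}, exactly one per
#'   treatment, all from the same fly and neuron.
#' @return list of class \code{RestingActivity}: \code{method}, \code{rate},
#'   and \code{components} (per-treatment pre-stimulus counts).
#' @export
restingActivityPrestim <- function(trains) {
  stopifnot(is.list(trains), length(trains) == 16L)
  treatments <- vapply(trains, function(x) x@treatment, character(1))
  if (anyDuplicated(treatments)) {
    stop("duplicate treatment(s): ",
         paste(unique(treatments[duplicated(treatments)]), collapse = ", "))
  }
  counts <- vapply(trains, function(x) {
    countSpikes(x, c(x@stimulusOnset - 1, x@stimulusOnset))
  }, numeric(1))
  names(counts) <- treatments
  structure(list(method = "prestim_16x1s", rate = sum(counts) / 16,
                 components = counts),
            class = "RestingActivity")
}

#' Consistency check between the two resting-activity estimators
#'
#' Compares the full-recording and pre-stimulus estimates for one fly/neuron.
#' Under the Poisson assumption each estimate's variance is count/T^2; the
#' check passes when the absolute difference is within \code{tol} pooled
#' standard errors. When both estimates are zero the difference is zero and
#' the check passes.
#'
#' @param a,b \code{RestingActivity} results for the same fly/neuron.
#' @param tol numeric, tolerance in pooled SEs; default
#'   \code{config@consistencyTol}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return list: both rates, \code{absDiff}, \code{relDiff}, \code{pooledSe}
#'   and logical \code{pass}.
#' @export
restingConsistency <- function(a, b, tol = NULL, config = analysisConfig()) {
  stopifnot(inherits(a, "RestingActivity"), inherits(b, "RestingActivity"))
  if (is.null(tol)) tol <- config@consistencyTol
  seOf <- function(x) {
    count <- sum(x$components[names(x$components) != "seconds"])
    secs <- if (x$method == "no_treatment_13s") 13 else 16
    sqrt(count) / secs
  }
  seA <- seOf(a)
  seB <- seOf(b)
  pooled <- sqrt(seA^2 + seB^2)
  d <- abs(a$rate - b$rate)
  list(rateA = a$rate, rateB = b$rate, absDiff = d,
       relDiff = if (max(a$rate, b$rate) > 0) d / max(a$rate, b$rate) else 0,
       pooledSe = pooled,
       pass = if (pooled > 0) d <= tol * pooled else d == 0)
}

#' Stimulus-aligned frequency time course
#'
#' Bins the spike train into fixed-width bins (default 25 ms) whose grid is
#' anchored at the stimulus onset, so traces from different recordings align
#' exactly by construction. Bins are half-open [left, right); a final partial
#' bin is dropped. Rates are count/binWidth; times are bin centers relative
#' to onset.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param binWidth numeric, seconds; default \code{config@binWidth}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return A \linkS4class{FrequencyTrace} at stage "raw".
#' @export
frequencyTrace <- function(train, binWidth = NULL, config = analysisConfig()) {
  stopifnot(is(train, "SpikeTrain"))
  if (is.null(binWidth)) binWidth <- config@binWidth
  if (binWidth <= 0) stop("binWidth must be > 0")
  on <- train@stimulusOnset
  kFirst <- ceiling(-on / binWidth - 1e-9)
  kLast <- floor((train@span - on) / binWidth + 1e-9) - 1
  if (kLast < kFirst) stop("binWidth too large for the recording span")
  k <- seq.int(kFirst, kLast)
  left <- on + k * binWidth
  counts <- vapply(left, function(a) {
    sum(train@spikeTimes >= a - 1e-12 & train@spikeTimes < a + binWidth - 1e-12)
  }, numeric(1))
  .frequencyTrace(times = (k + 0.5) * binWidth, rate = counts / binWidth,
                  binWidth = binWidth, stage = "raw",
                  labels = list(fly = train@fly, sensillum = train@sensillum,
                                neuron = train@neuron,
                                treatment = train@treatment,
                                cohort = train@cohort))
}

#' Average frequency traces across recordings
#'
#' Per-bin mean across traces sharing an identical bin grid and stage, with
#' the per-bin SEM (NA for a single trace).
#'
#' @param traces list of \linkS4class{FrequencyTrace}.
#' @return list: \code{trace} (mean \linkS4class{FrequencyTrace}), \code{sem}
#'   numeric per bin, \code{n}.
#' @export
meanTrace <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  ref <- traces[[1]]
  for (tr in traces) {
    if (tr@stage != ref@stage) stop("stage mismatch across traces")
    if (length(tr@times) != length(ref@times) ||
        any(abs(tr@times - ref@times) > 1e-9)) {
      stop("bin-grid mismatch across traces")
    }
  }
  m <- vapply(traces, binRate, numeric(length(ref@times)))
  m <- matrix(m, nrow = length(ref@times))
  n <- ncol(m)
  mu <- rowMeans(m)
  sem <- if (n == 1L) rep(NA_real_, nrow(m)) else apply(m, 1, stats::sd) / sqrt(n)
  list(trace = .frequencyTrace(ref@times, mu, ref@binWidth, ref@stage,
                               labels = c(ref@labels[c("sensillum", "cohort")],
                                          list(n = n))),
       sem = sem, n = n)
}
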