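#' Mean air-gust trace for one sensillum
#'
#' Per-bin arithmetic mean of the raw frequency traces recorded under the
#' blank air-gust treatment, pooled across flies of one sensillum (and, by
#' the caller's grouping, one cohort). This is the mechanical-response
#' template subtracted from all other traces.
#'
#' @param traces list of raw-stage \linkS4class{FrequencyTrace} from air-gust
#'   recordings of one sensillum on an identical bin grid.
#' @return A \linkS4class{FrequencyTrace} (stage "raw").
#' @export
meanGustTrace <- function(traces) {
  if (!length(traces)) stop("no air-gust traces for this sensillum")
  sens <- unique(vapply(traces, function(x) x@labels$sensillum %||% "",
                        character(1)))
  if (length(sens) > 1L) stop("traces span several sensilla: ",
                              paste(sens, collapse = ", "))
  if (any(vapply(traces, function(x) x@stage, character(1)) != "raw")) {
    stop("gust averaging expects raw-stage traces")
  }
  meanTrace(traces)$trace
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subtract the mean air-gust trace from a frequency trace
#'
#' Per-bin subtraction on an identical grid. The output stage is
#' "gust_corrected"; values may be negative by design (no clipping), so
#' downstream areas can cancel correctly.
#'
#' @param trace a raw-stage \linkS4class{FrequencyTrace}.
#' @param gustMean the sensillum's mean gust \linkS4class{FrequencyTrace}.
#' @return A \linkS4class{FrequencyTrace} at stage "gust_corrected".
#' @export
gustCorrect <- function(trace, gustMean) {
  stopifnot(is(trace, "FrequencyTrace"), is(gustMean, "FrequencyTrace"))
  if (trace@stage != "raw") stop("gust correction applies to raw traces")
  if (length(trace@times) != length(gustMean@times) ||
      any(abs(trace@times - gustMean@times) > 1e-9)) {
    stop("bin-grid mismatch between trace and gust mean")
  }
  .frequencyTrace(trace@times, trace@rate - gustMean@rate,
                  trace@binWidth, "gust_corrected", trace@labels)
}

#' Rolling-average smoothing of a frequency trace
#'
#' Centered rolling mean over window/binWidth consecutive bins (default
#' 400 ms over 25 ms bins, k = 16), computed with \code{zoo::rollmean}. The
#' output is defined only where the full window fits, so the trace shortens
#' by k - 1 bins; output times are the means of the contributing bin times.
#'
#' @param trace a \linkS4class{FrequencyTrace} (any stage).
#' @param window numeric, seconds; default \code{config@smoothWindow}. Must
#'   be an integer multiple of the bin width.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return A \linkS4class{FrequencyTrace} at stage "smoothed".
#' @export
smoothTrace <- function(trace, window = NULL, config = analysisConfig()) {
  stopifnot(is(trace, "FrequencyTrace"))
  if (is.null(window)) window <- config@smoothWindow
  k <- window / trace@binWidth
  if (abs(k - round(k)) > 1e-9 || round(k) < 1) {
    stop("smoothing window must be a positive integer multiple of the bin width")
  }
  k <- as.integer(round(k))
  if (k > length(trace@rate)) stop("smoothing window longer than the trace")
  rate <- as.numeric(zoo::rollmean(trace@rate, k))
  times <- as.numeric(zoo::rollmean(trace@times, k))
  .frequencyTrace(times, rate, trace@binWidth, "smoothed", trace@labels)
}

#' Peak and area-under-curve of a frequency trace
#'
#' Surveys only samples inside the stage's response window — stimulus onset
#' to 1 s after onset for raw and gust-corrected traces, and 0.5 s before to
#' 1 s after onset for smoothed traces (the rolling average shifts
#' responses). The peak is the maximum rate over in-window samples; the AUC
#' is the trapezoidal integral (\code{pracma::trapz}) of rate over time, in
#' spikes. Window endpoints are inclusive.
#'
#' @param trace a \linkS4class{FrequencyTrace}.
#' @param config an \linkS4class{AnalysisConfig} providing the windows.
#' @return data.frame row: \code{stage}, \code{peak} (spikes/s), \code{auc}
#'   (spikes), \code{windowStart}, \code{windowEnd} (s relative to onset),
#'   plus the trace's labels.
#' @export
extractMetrics <- function(trace, config = analysisConfig()) {
  stopifnot(is(trace, "FrequencyTrace"))
  win <- if (trace@stage == "smoothed") {
    config@responseWindowSmoothed
  } else {
    config@responseWindowRaw
  }
  inWin <- trace@times >= win[1] - 1e-9 & trace@times <= win[2] + 1e-9
  if (!any(inWin)) stop("no trace samples inside the response window")
  tt <- trace@times[inWin]
  rr <- trace@rate[inWin]
  lb <- trace@labels
  data.frame(fly = lb$fly %||% "", sensillum = lb$sensillum %||% "",
             neuron = lb$neuron %||% "", treatment = lb$treatment %||% "",
             cohort = lb$cohort %||% "", stage = trace@stage,
             peak = max(rr), auc = pracma::trapz(tt, rr),
             windowStart = win[1], windowEnd = win[2],
             stringsAsFactors = FALSE)
}

#' Three-step air-gust correction workflow
#'
#' Runs the full mechanoresponse-dissociation pipeline over a set of spike
#' trains: (1) raw 25 ms frequency traces and their metrics; (2) subtraction
#' of the mean air-gust trace, computed per sensillum within each cohort,
#' and metrics of the corrected traces; (3) 400 ms rolling-average smoothing
#' of the corrected traces and metrics over the widened window. Deterministic
#' given its inputs.
#'
#' @param trains list of \linkS4class{SpikeTrain} covering at least one
#'   air-gust recording per (cohort, sensillum) group.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param gustLabel treatment label of the blank mechanical stimulus.
#' @return data.frame with one row per (train, stage): labels, \code{stage},
#'   \code{peak}, \code{auc} and the response window used.
#' @export
runThreeStep <- function(trains, config = analysisConfig(),
                         gustLabel = "air gust") {
  stopifnot(is.list(trains), length(trains) >= 1L)
  raw <- lapply(trains, frequencyTrace, config = config)
  key <- vapply(trains, function(x) paste(x@cohort, x@sensillum, sep = "/"),
                character(1))
  isGust <- vapply(trains, function(x) x@treatment == gustLabel, logical(1))
  gustMeans <- list()
  for (grp in unique(key)) {
    sel <- which(key == grp & isGust)
    if (!length(sel)) {
      stop("no '", gustLabel, "' recordings for group ", grp)
    }
    gustMeans[[grp]] <- meanGustTrace(raw[sel])
  }
  rows <- vector("list", 3L * length(trains))
  for (i in seq_along(trains)) {
    corrected <- gustCorrect(raw[[i]], gustMeans[[key[i]]])
    smoothed <- smoothTrace(corrected, config = config)
    rows[[3 * i - 2]] <- extractMetrics(raw[[i]], config)
    rows[[3 * i - 1]] <- extractMetrics(corrected, config)
    rows[[3 * i]] <- extractMetrics(smoothed, config)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Heatshock-minus-control summary of response metrics
#'
#' For each (sensillum, treatment) cell of the design grid at one processing
#' stage, the difference of cohort means, heatshock minus control, for the
#' peak rate and the AUC separately. A cell with a missing cohort is reported
#' with NA deltas and \code{absent} naming the missing cohort, never as zero.
#'
#' @param metrics data.frame from \code{\link{runThreeStep}}.
#' @param stage processing stage to summarize (default "smoothed").
#' @return data.frame: \code{sensillum}, \code{treatment}, \code{deltaPeak},
#'   \code{deltaAuc}, \code{nHeatshock}, \code{nControl}, \code{absent}.
#' @export
deltaSummary <- function(metrics, stage = "smoothed") {
  m <- metrics[metrics$stage == stage, , drop = FALSE]
  if (!nrow(m)) stop("no metrics at stage ", stage)
  cells <- unique(m[, c("sensillum", "treatment")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- m[m$sensillum == cells$sensillum[i] &
               m$treatment == cells$treatment[i], ]
    hs <- sub[sub$cohort == "heatshock", ]
    ct <- sub[sub$cohort == "control", ]
    absent <- c(if (!nrow(hs)) "heatshock", if (!nrow(ct)) "control")
    data.frame(sensillum = cells$sensillum[i],
               treatment = cells$treatment[i],
               deltaPeak = if (length(absent)) NA_real_ else
                 mean(hs$peak) - mean(ct$peak),
               deltaAuc = if (length(absent)) NA_real_ else
                 mean(hs$auc) - mean(ct$auc),
               nHeatshock = nrow(hs), nControl = nrow(ct),
               absent = if (length(absent)) paste(absent, collapse = ",")
                        else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
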