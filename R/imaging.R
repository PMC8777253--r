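#' Default baseline (F0) frame window
#'
#' The standard placement: \code{f0Frames} consecutive frames ending
#' \code{f0Gap} frames before the frame of the first stimulus event (50 s of
#' "resting" signal at the default 10 frames x 5 s).
#'
#' @param rec an \linkS4class{ImagingRecording}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return integer vector of frame indices.
#' @export
defaultF0Window <- function(rec, config = analysisConfig()) {
  onset <- firstStimulusOnset(rec@events)
  if (!is.finite(onset)) {
    return(seq_len(min(config@f0Frames, nFrames(rec))))
  }
  onsetFrame <- floor(onset / rec@frameInterval) + 1L
  last <- onsetFrame - config@f0Gap - 1L
  first <- last - config@f0Frames + 1L
  if (first < 1L) {
    stop(sprintf(
      "cannot place a %d-frame baseline window before the stimulus at %g s",
      config@f0Frames, onset))
  }
  seq.int(first, last)
}

#' Baseline-normalize an imaging recording (dF/F0)
#'
#' For each cell ROI r and frame t the background ROI is subtracted
#' per frame, F(r,t) = raw(r,t) - raw(bg,t); the baseline F0(r) is the mean
#' of F(r,.) over the F0 window; and the returned value is the percent change
#' dff(r,t) = 100 * (F(r,t) - F0(r)) / F0(r).
#'
#' @param rec an \linkS4class{ImagingRecording}.
#' @param f0Window integer frame indices; default from
#'   \code{\link{defaultF0Window}}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param backgroundMode "per_frame" (default) subtracts the background trace
#'   frame by frame; "mean" subtracts its temporal mean.
#' @return A \linkS4class{DffTraces}.
#' @examples
#' m <- cbind(bg = rep(2, 12), roi1 = c(rep(10, 10), 12, 12))
#' rec <- imagingRecording(m, frameInterval = 5,
#'   events = stimulusEvents("VUAA1", 50, 0, "odor"))
#' dffMatrix(computeDff(rec))[11:12, ]  # 25 percent
#' @export
computeDff <- function(rec, f0Window = NULL, config = analysisConfig(),
                       backgroundMode = c("per_frame", "mean")) {
  stopifnot(is(rec, "ImagingRecording"))
  backgroundMode <- match.arg(backgroundMode)
  if (is.null(f0Window)) f0Window <- defaultF0Window(rec, config)
  f0Window <- as.integer(f0Window)
  if (any(f0Window < 1L) || any(f0Window > nFrames(rec))) {
    stop("f0Window out of the recording's frame range")
  }
  onset <- firstStimulusOnset(rec@events)
  winEnd <- max(f0Window) * rec@frameInterval
  if (is.finite(onset) && winEnd > onset + 1e-9) {
    stop("f0Window overlaps the first stimulus")
  }
  m <- rec@traces
  bg <- m[, rec@backgroundRoi]
  if (backgroundMode == "mean") bg <- rep(mean(bg), length(bg))
  cells <- m[, cellRois(rec), drop = FALSE]
  F <- cells - bg
  f0 <- colMeans(F[f0Window, , drop = FALSE])
  low <- f0 <= 0
  if (any(low)) {
    stop("degenerate baseline (F0 <= 0) for ROI(s): ",
         paste(colnames(cells)[low], collapse = ", "))
  }
  dff <- 100 * sweep(sweep(F, 2, f0, "-"), 2, f0, "/")
  new("DffTraces", dff = dff, f0Window = f0Window, f0Values = f0,
      frameInterval = rec@frameInterval, events = rec@events)
}

#' Classify ROIs as responders or non-responders
#'
#' Formalizes the by-eye responder call: a cell is a responder when its peak
#' absolute dF/F0 within the response window reaches at least \code{k}
#' baseline standard deviations (SD of its dF/F0 over the F0 window). With
#' \code{expectedSign} set (+1 or -1) only excursions of that sign count,
#' matching the known flux direction of a preset.
#'
#' The baseline SD is computed over the F0 window. With the default
#' \code{sdMode = "pooled"} the per-ROI variances are pooled (root mean
#' square) across all ROIs: a single-ROI SD estimated from a 10-frame window
#' has only 9 degrees of freedom, making the score's denominator so variable
#' that flat cells are sporadically called responders, whereas the noise
#' level is common to all ROIs of a recording and pools stably.
#' \code{sdMode = "per_roi"} uses each ROI's own baseline SD.
#'
#' @param dff a \linkS4class{DffTraces}.
#' @param window numeric(2), response window in seconds from recording start;
#'   default from the first stimulus onset to the end of the recording.
#' @param k threshold multiplier; default \code{config@responderK}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param expectedSign 0 (default, unsigned), +1 or -1.
#' @param sdMode "pooled" (default) or "per_roi"; see above.
#' @return data.frame with per-ROI \code{roi}, \code{score}, \code{label}
#'   ("responder"/"non_responder") and the \code{threshold} used. A zero
#'   baseline SD with signal in the window yields score \code{Inf}
#'   (responder); zero SD with a flat window yields a non-responder.
#' @export
classifyResponders <- function(dff, window = NULL, k = NULL,
                               config = analysisConfig(), expectedSign = 0,
                               sdMode = c("pooled", "per_roi")) {
  stopifnot(is(dff, "DffTraces"))
  sdMode <- match.arg(sdMode)
  if (is.null(k)) k <- config@responderK
  tt <- frameTimes(dff)
  if (is.null(window)) {
    onset <- firstStimulusOnset(dff@events)
    if (!is.finite(onset)) stop("no stimulus event; supply a response window")
    window <- c(onset, max(tt))
  }
  inWin <- tt >= window[1] & tt <= window[2]
  if (!any(inWin)) stop("response window contains no frames")
  m <- dff@dff
  base <- m[dff@f0Window, , drop = FALSE]
  sdBase <- apply(base, 2, stats::sd)
  if (sdMode == "pooled") {
    sdBase <- rep(sqrt(mean(sdBase^2)), length(sdBase))
  }
  resp <- m[inWin, , drop = FALSE]
  excur <- if (expectedSign > 0) {
    apply(resp, 2, max)
  } else if (expectedSign < 0) {
    apply(-resp, 2, max)
  } else {
    apply(abs(resp), 2, max)
  }
  excur <- pmax(excur, 0)
  score <- ifelse(sdBase > 0, excur / sdBase,
                  ifelse(excur > 1e-12, Inf, 0))
  data.frame(roi = colnames(m), score = score,
             label = ifelse(score >= k, "responder", "non_responder"),
             threshold = k, row.names = NULL, stringsAsFactors = FALSE)
}

#' Average traces across replicates or cells
#'
#' Per-frame mean and standard error of the mean across units, where a unit
#' is either one replicate antenna's average trace or one cell ROI. With a
#' single unit the SEM is undefined and reported as \code{NA}, not 0.
#'
#' @param traces numeric matrix (frames x units) or list of equal-length
#'   numeric vectors.
#' @param unitMode "per_replicate" or "per_cell" (bookkeeping label).
#' @param times optional numeric vector of frame times to carry through.
#' @return data.frame with columns \code{time} (if given), \code{mean},
#'   \code{sem}; attributes \code{n} and \code{unitMode}.
#' @examples
#' aggregateTraces(cbind(c(0, 2), c(2, 4)))
#' @export
aggregateTraces <- function(traces, unitMode = c("per_replicate", "per_cell"),
                            times = NULL) {
  unitMode <- match.arg(unitMode)
  if (is.list(traces)) {
    lens <- lengths(traces)
    if (length(unique(lens)) != 1L) {
      stop("all unit traces must have the same length")
    }
    traces <- do.call(cbind, traces)
  }
  stopifnot(is.matrix(traces), ncol(traces) >= 1L)
  n <- ncol(traces)
  mu <- rowMeans(traces)
  sem <- if (n == 1L) {
    rep(NA_real_, nrow(traces))
  } else {
    apply(traces, 1, stats::sd) / sqrt(n)
  }
  out <- data.frame(mean = mu, sem = sem)
  if (!is.null(times)) {
    stopifnot(length(times) == nrow(traces))
    out <- cbind(data.frame(time = times), out)
  }
  attr(out, "n") <- n
  attr(out, "unitMode") <- unitMode
  out
}

#' Time of the strongest population response
#'
#' Scans a post-stimulus search window and returns the frame time at which
#' the largest absolute mean dF/F0 across all conditions is reached — the
#' timepoint at which dose-response curves are read out. Ties break to the
#' earliest frame.
#'
#' @param aggByCondition named list of \code{\link{aggregateTraces}} results,
#'   each with a \code{time} column on a shared frame grid.
#' @param searchWindow numeric(2), seconds from recording start.
#' @return numeric, the selected frame time in seconds.
#' @export
findExtremumTime <- function(aggByCondition, searchWindow) {
  stopifnot(is.list(aggByCondition), length(aggByCondition) >= 1L)
  tt <- aggByCondition[[1]]$time
  if (is.null(tt)) stop("aggregates must carry a time column")
  for (a in aggByCondition) {
    if (is.null(a$time) || length(a$time) != length(tt) ||
        any(abs(a$time - tt) > 1e-9)) {
      stop("all conditions must share the same frame times")
    }
  }
  inWin <- tt >= searchWindow[1] & tt <= searchWindow[2]
  if (!any(inWin)) stop("empty search window")
  absMean <- sapply(aggByCondition, function(a) abs(a$mean))
  envelope <- apply(as.matrix(absMean), 1, max)
  cand <- which(inWin)
  best <- cand[which.max(envelope[cand])]  # which.max: earliest on ties
  tt[best]
}

#' Extract a dose-response curve at a fixed readout time
#'
#' For each concentration, the mean and SEM of dF/F0 at \code{evalTime}
#' across units (cells or replicates). \code{evalTime} must be an acquired
#' frame time in every recording; no interpolation is performed.
#'
#' @param dffByConcentration named list (names = concentrations in mM) of
#'   \linkS4class{DffTraces} or lists thereof.
#' @param evalTime numeric, seconds from recording start.
#' @return data.frame sorted by concentration with columns
#'   \code{concentration}, \code{mean}, \code{sem}, \code{n}; attribute
#'   \code{evalTime}.
#' @export
doseResponse <- function(dffByConcentration, evalTime) {
  stopifnot(length(dffByConcentration) >= 1L)
  conc <- suppressWarnings(as.numeric(names(dffByConcentration)))
  if (any(is.na(conc))) stop("list names must be numeric concentrations (mM)")
  rows <- lapply(seq_along(conc), function(i) {
    entry <- dffByConcentration[[i]]
    if (is(entry, "DffTraces")) entry <- list(entry)
    vals <- unlist(lapply(entry, function(d) {
      tt <- frameTimes(d)
      j <- which(abs(tt - evalTime) < 1e-9)
      if (length(j) != 1L) {
        stop(sprintf(
          "evalTime %g s is not an acquired frame; interpolation refused",
          evalTime))
      }
      d@dff[j, ]
    }))
    n <- length(vals)
    data.frame(concentration = conc[i], mean = mean(vals),
               sem = if (n > 1) stats::sd(vals) / sqrt(n) else NA_real_,
               n = n)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$concentration), , drop = FALSE]
  if (anyDuplicated(out$concentration)) stop("duplicate concentrations")
  rownames(out) <- NULL
  attr(out, "evalTime") <- evalTime
  out
}
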