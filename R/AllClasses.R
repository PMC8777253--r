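#' @import methods
NULL

.MODALITIES <- c("odor", "solvent", "mechanical", "none")
.STAGES <- c("raw", "gust_corrected", "smoothed")

#' Analysis configuration
#'
#' Holds every fixed constant of the pipeline so that no stage carries hidden
#' literals: the baseline (F0) window length, the spike-binning width, the
#' rolling-average span, the stage-dependent response windows for peak/AUC
#' extraction, and the responder-classification threshold.
#'
#' @slot f0Frames integer, number of imaging frames in the baseline window
#'   (default 10 frames, i.e. 50 s at the 5 s frame interval).
#' @slot f0Gap integer, frames between the end of the baseline window and the
#'   frame of the first stimulus (default 1: the window ends one frame before
#'   the first stimulation).
#' @slot binWidth numeric, spike-histogram bin width in seconds (default 0.025).
#' @slot smoothWindow numeric, rolling-average span in seconds (default 0.400);
#'   must be an integer multiple of \code{binWidth}.
#' @slot responseWindowRaw numeric(2), peak/AUC window in seconds relative to
#'   stimulus onset for raw and gust-corrected traces (default c(0, 1)).
#' @slot responseWindowSmoothed numeric(2), the widened window used for
#'   smoothed traces (default c(-0.5, 1)), accommodating the shift introduced
#'   by the rolling average.
#' @slot responderK numeric, responder threshold: a cell is a responder when
#'   its peak |dF/F0| in the response window is at least \code{responderK}
#'   baseline standard deviations (default 5).
#' @slot consistencyTol numeric, resting-activity consistency tolerance in
#'   multiples of the pooled Poisson standard error (default 2).
#' @slot rngSeed integer, default seed for simulations.
#' @export
setClass("AnalysisConfig",
  representation(
    f0Frames = "integer",
    f0Gap = "integer",
    binWidth = "numeric",
    smoothWindow = "numeric",
    responseWindowRaw = "numeric",
    responseWindowSmoothed = "numeric",
    responderK = "numeric",
    consistencyTol = "numeric",
    rngSeed = "integer"
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (object@f0Frames < 1L) msg <- c(msg, "f0Frames must be >= 1")
  if (object@f0Gap < 0L) msg <- c(msg, "f0Gap must be >= 0")
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be > 0")
  k <- object@smoothWindow / object@binWidth
  if (abs(k - round(k)) > 1e-9 || round(k) < 1) {
    msg <- c(msg, "smoothWindow must be a positive integer multiple of binWidth")
  }
  for (w in list(object@responseWindowRaw, object@responseWindowSmoothed)) {
    if (length(w) != 2L || w[1] >= w[2]) {
      msg <- c(msg, "response windows must be length-2 with start < end")
    }
  }
  if (object@responderK <= 0) msg <- c(msg, "responderK must be > 0")
  if (object@consistencyTol <= 0) msg <- c(msg, "consistencyTol must be > 0")
  if (length(msg)) msg else TRUE
})

#' Imaging recording
#'
#' A frames-by-ROIs matrix of average fluorescence values (arbitrary units) as
#' exported by ROI-averaging acquisition software, together with the frame
#' interval, the name of the designated background ROI (a region outside the
#' tissue), the stimulus-event schedule and free-form metadata
#' (driver/indicator/genotype).
#'
#' @slot traces numeric matrix, frames x ROIs; column names are ROI names and
#'   exactly one column is the background ROI.
#' @slot frameInterval numeric, seconds between frames (default 5).
#' @slot backgroundRoi character, name of the background ROI column.
#' @slot events data.frame with columns \code{label}, \code{onset_time},
#'   \code{duration}, \code{modality} (see \code{\link{stimulusEvents}}).
#' @slot meta list of free-form metadata.
#' @export
setClass("ImagingRecording",
  representation(
    traces = "matrix",
    frameInterval = "numeric",
    backgroundRoi = "character",
    events = "data.frame",
    meta = "list"
  )
)

setValidity("ImagingRecording", function(object) {
  msg <- character()
  m <- object@traces
  if (!is.numeric(m) || is.null(colnames(m))) {
    msg <- c(msg, "traces must be a numeric matrix with ROI column names")
  } else {
    if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate ROI names")
    nbg <- sum(colnames(m) == object@backgroundRoi)
    if (nbg != 1L) {
      msg <- c(msg, sprintf(
        "exactly one background ROI required; '%s' matches %d columns",
        object@backgroundRoi, nbg))
    }
    if (!all(is.finite(m))) msg <- c(msg, "all fluorescence values must be finite")
  }
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0) {
    msg <- c(msg, "frameInterval must be a positive scalar")
  }
  ev <- try(validateEvents(object@events,
    span = nrow(m) * object@frameInterval), silent = TRUE)
  if (inherits(ev, "try-error")) {
    msg <- c(msg, conditionMessage(attr(ev, "condition")))
  }
  if (length(msg)) msg else TRUE
})

#' Baseline-normalized fluorescence traces
#'
#' Percent change from baseline (dF/F0) per cell ROI, after per-frame
#' background subtraction. Carries the frame window used as F0, the per-ROI
#' baseline fluorescence it produced, and the inherited event schedule.
#'
#' @slot dff numeric matrix, frames x cell ROIs, in percent.
#' @slot f0Window integer vector of frame indices used as the baseline window.
#' @slot f0Values numeric, per-ROI baseline fluorescence (a.u., background
#'   subtracted); must be strictly positive.
#' @slot frameInterval numeric, seconds.
#' @slot events data.frame, stimulus events inherited from the recording.
#' @export
setClass("DffTraces",
  representation(
    dff = "matrix",
    f0Window = "integer",
    f0Values = "numeric",
    frameInterval = "numeric",
    events = "data.frame"
  )
)

setValidity("DffTraces", function(object) {
  msg <- character()
  if (any(object@f0Values <= 0)) msg <- c(msg, "f0Values must be > 0")
  if (any(object@f0Window < 1L) || any(object@f0Window > nrow(object@dff))) {
    msg <- c(msg, "f0Window out of range")
  }
  if (ncol(object@dff) > 0) {
    base <- colMeans(object@dff[object@f0Window, , drop = FALSE])
    if (any(abs(base) > 1e-9)) {
      msg <- c(msg, "mean dF/F0 over the baseline window must be 0 for every ROI")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Spike train
#'
#' Sorted spike times from one single-sensillum recording, with the recording
#' span (default 13 s: 3 s pre- and 10 s post-stimulus), the stimulus-onset
#' timestamp and experimental labels.
#'
#' @slot spikeTimes numeric, strictly increasing, in seconds from recording
#'   start, all within [0, span].
#' @slot span numeric, recording duration in seconds (default 13).
#' @slot stimulusOnset numeric, seconds (default 3).
#' @slot stimulusDuration numeric, seconds (default 0.5).
#' @slot treatment,sensillum,neuron,cohort,genotype,fly character labels;
#'   \code{cohort} is one of "control", "heatshock".
#' @export
setClass("SpikeTrain",
  representation(
    spikeTimes = "numeric",
    span = "numeric",
    stimulusOnset = "numeric",
    stimulusDuration = "numeric",
    treatment = "character",
    sensillum = "character",
    neuron = "character",
    cohort = "character",
    genotype = "character",
    fly = "character"
  )
)

setValidity("SpikeTrain", function(object) {
  msg <- character()
  st <- object@spikeTimes
  if (length(st)) {
    if (any(!is.finite(st))) msg <- c(msg, "spike times must be finite")
    if (any(st < 0) || any(st > object@span)) {
      msg <- c(msg, "spike times must lie within [0, span]")
    }
    if (any(diff(st) <= 0)) {
      msg <- c(msg, "spike times must be strictly increasing")
    }
  }
  if (object@span <= 0) msg <- c(msg, "span must be > 0")
  if (object@stimulusOnset < 0 || object@stimulusOnset > object@span) {
    msg <- c(msg, "stimulusOnset must lie within the span")
  }
  if (!object@cohort %in% c("control", "heatshock")) {
    msg <- c(msg, "cohort must be 'control' or 'heatshock'")
  }
  if (length(msg)) msg else TRUE
})

#' Stimulus-aligned firing-rate trace
#'
#' A peristimulus frequency time course: spike counts in fixed-width bins
#' (default 25 ms), expressed as spikes/s, with bin centers reported relative
#' to stimulus onset. The bin grid is anchored at the stimulus onset so traces
#' from different recordings align exactly. The \code{stage} tag records the
#' processing stage: \code{raw}, \code{gust_corrected} (after subtraction of
#' the mean air-gust trace; values may be negative) or \code{smoothed}.
#'
#' @slot times numeric, bin centers in seconds relative to stimulus onset.
#' @slot rate numeric, spikes/s per bin.
#' @slot binWidth numeric, seconds.
#' @slot stage character, one of "raw", "gust_corrected", "smoothed".
#' @slot labels list of experimental labels carried from the source train.
#' @export
setClass("FrequencyTrace",
  representation(
    times = "numeric",
    rate = "numeric",
    binWidth = "numeric",
    stage = "character",
    labels = "list"
  )
)

setValidity("FrequencyTrace", function(object) {
  msg <- character()
  if (length(object@times) != length(object@rate)) {
    msg <- c(msg, "times and rate must have equal length")
  }
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be > 0")
  if (!object@stage %in% .STAGES) {
    msg <- c(msg, sprintf("stage must be one of %s", paste(.STAGES, collapse = ", ")))
  }
  if (object@stage == "raw" && length(object@rate) && any(object@rate < -1e-12)) {
    msg <- c(msg, "raw-stage rates must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Imaging simulation parameters
#'
#' Parameters of the synthetic fluorescence generator. Each responder cell's
#' trace is background + baseline * bleach(t) + amplitude * K(t - onset) +
#' noise, where K is a difference-of-exponentials transient kernel normalized
#' to peak 1 and amplitude is expressed in percent of baseline (signed:
#' positive = influx, negative = efflux). Presets fix the sign (or zero) of
#' the transient and the responder fraction per cell type and cation.
#'
#' @slot nCells integer, number of cell ROIs.
#' @slot responderFraction numeric in [0, 1].
#' @slot transientAmplitude numeric, percent of baseline, signed.
#' @slot riseTau,decayTau numeric, kernel time constants in seconds.
#' @slot baselineLevel,backgroundLevel numeric, a.u.
#' @slot bleachRate numeric, fractional photobleaching decay per frame
#'   (0 disables bleaching).
#' @slot noiseSd numeric, i.i.d. Gaussian noise SD per frame, a.u.
#' @slot frameInterval numeric, seconds; \code{nFrames} integer.
#' @slot events data.frame of stimulus events.
#' @slot preset character, one of "osn_ca", "osn_k", "tormogen_ca",
#'   "tormogen_k", "thecogen_ca", "thecogen_k" or "" (no preset).
#' @export
setClass("ImagingSimParams",
  representation(
    nCells = "integer",
    responderFraction = "numeric",
    transientAmplitude = "numeric",
    riseTau = "numeric",
    decayTau = "numeric",
    baselineLevel = "numeric",
    backgroundLevel = "numeric",
    bleachRate = "numeric",
    noiseSd = "numeric",
    frameInterval = "numeric",
    nFrames = "integer",
    events = "data.frame",
    preset = "character"
  )
)

setValidity("ImagingSimParams", function(object) {
  msg <- character()
  if (object@nCells < 1L) msg <- c(msg, "nCells must be >= 1")
  if (object@responderFraction < 0 || object@responderFraction > 1) {
    msg <- c(msg, "responderFraction must be in [0, 1]")
  }
  if (object@riseTau <= 0 || object@decayTau <= 0) msg <- c(msg, "taus must be > 0")
  if (object@riseTau >= object@decayTau) {
    msg <- c(msg, "riseTau must be smaller than decayTau")
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@baselineLevel <= 0) msg <- c(msg, "baselineLevel must be > 0")
  if (object@bleachRate < 0 || object@bleachRate >= 1) {
    msg <- c(msg, "bleachRate must be in [0, 1)")
  }
  if (nzchar(object@preset)) {
    sgn <- .presetSign(object@preset)
    amp <- object@transientAmplitude
    if (sgn == 0 && amp != 0) {
      msg <- c(msg, sprintf("preset '%s' is flux-free but amplitude is %g",
                            object@preset, amp))
    }
    if (sgn != 0 && amp != 0 && sign(amp) != sgn) {
      msg <- c(msg, sprintf("preset '%s' requires amplitude sign %+d",
                            object@preset, sgn))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Spike-train simulation parameters
#'
#' Parameters of the inhomogeneous-Poisson spike-train generator. The rate is
#' lambda(t) = baselineRate + odorGain * A(t - onset) + gMech * M(t - onset),
#' with A and M peak-normalized alpha-function kernels that are zero before
#' stimulus onset; gMech is \code{mechGain} for the control cohort and
#' \code{mechGainHeatshock} for the heatshock (thecogen-ablated) cohort, which
#' encodes the gained mechanosensitivity of the ablated flies.
#'
#' @slot baselineRate numeric, spontaneous rate in spikes/s.
#' @slot odorGain numeric, peak added odor-response rate, spikes/s.
#' @slot odorTau numeric, alpha-kernel time constant in seconds (default 0.1,
#'   giving a response duration of roughly 0.4-0.5 s).
#' @slot mechGain,mechGainHeatshock numeric, peak added mechanical-response
#'   rate per cohort, spikes/s.
#' @slot mechTau numeric, mechanical kernel time constant (default 0.05 s,
#'   a briefer ~0.2 s gust transient).
#' @slot span,stimulusOnset,stimulusDuration numeric, seconds.
#' @export
setClass("SpikeSimParams",
  representation(
    baselineRate = "numeric",
    odorGain = "numeric",
    odorTau = "numeric",
    mechGain = "numeric",
    mechGainHeatshock = "numeric",
    mechTau = "numeric",
    span = "numeric",
    stimulusOnset = "numeric",
    stimulusDuration = "numeric"
  )
)

setValidity("SpikeSimParams", function(object) {
  msg <- character()
  rates <- c(object@baselineRate, object@odorGain, object@mechGain,
             object@mechGainHeatshock)
  if (any(rates < 0)) msg <- c(msg, "all rates and gains must be >= 0")
  if (object@odorTau <= 0 || object@mechTau <= 0) msg <- c(msg, "kernel taus must be > 0")
  if (object@span <= 0) msg <- c(msg, "span must be > 0")
  if (object@stimulusOnset < 0 || object@stimulusOnset > object@span) {
    msg <- c(msg, "stimulusOnset must lie within the span")
  }
  if (length(msg)) msg else TRUE
})
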