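# Cell-type presets: transient sign (+ influx, - efflux, 0 no flux), the
# fraction of cells that respond, and a default amplitude magnitude (% of
# baseline). The tormogen Ca2+ responder fraction reflects the 42%
# non-responding subpopulation; the thecogen K+ amplitude is small because
# that influx is a marginal signal.
.IMAGING_PRESETS <- list(
  osn_ca      = list(sign = +1, responderFraction = 1.00, amplitude = 30),
  osn_k       = list(sign = -1, responderFraction = 1.00, amplitude = 20),
  tormogen_ca = list(sign = +1, responderFraction = 0.58, amplitude = 30),
  tormogen_k  = list(sign =  0, responderFraction = 0.00, amplitude = 0),
  thecogen_ca = list(sign =  0, responderFraction = 0.00, amplitude = 0),
  thecogen_k  = list(sign = +1, responderFraction = 1.00, amplitude = 8)
)

.presetSign <- function(preset) {
  if (!preset %in% names(.IMAGING_PRESETS)) {
    stop("unknown imaging preset: ", preset)
  }
  .IMAGING_PRESETS[[preset]]$sign
}

#' Peak-normalized fluorescence transient kernel
#'
#' Difference of exponentials exp(-t/decayTau) - exp(-t/riseTau), zero for
#' t < 0 and scaled to peak at exactly 1. With the defaults (rise 40 s,
#' decay 240 s) the kernel peaks 86 s after onset, so on a 5 s frame grid the
#' sampled maximum falls on the 85 s frame.
#'
#' @param t numeric, seconds since stimulus onset (may be negative).
#' @param riseTau,decayTau numeric, seconds, riseTau < decayTau.
#' @return numeric, kernel values in [0, 1].
#' @export
transientKernel <- function(t, riseTau = 40, decayTau = 240) {
  stopifnot(riseTau > 0, decayTau > riseTau)
  tPeak <- riseTau * decayTau / (decayTau - riseTau) * log(decayTau / riseTau)
  peak <- exp(-tPeak / decayTau) - exp(-tPeak / riseTau)
  k <- ifelse(t < 0, 0, exp(-t / decayTau) - exp(-t / riseTau))
  k / peak
}

#' Build imaging simulation parameters
#'
#' A \code{preset} fixes the transient sign and responder fraction for one
#' cell type and cation (see \linkS4class{ImagingSimParams}); explicit
#' arguments override the preset's amplitude magnitude and responder fraction
#' but must respect its sign.
#'
#' @param nCells integer, number of cell ROIs.
#' @param preset character preset name, or "" for fully manual parameters.
#' @param responderFraction,transientAmplitude,riseTau,decayTau,baselineLevel,backgroundLevel,bleachRate,noiseSd,frameInterval,nFrames
#'   see \linkS4class{ImagingSimParams}; defaults emulate the standard
#'   protocol (180 frames at 5 s, baseline 100 a.u., background 10 a.u.,
#'   noise SD 2 a.u., no bleaching).
#' @param events events data.frame; default one VUAA1 application at 300 s.
#' @return An \linkS4class{ImagingSimParams}.
#' @examples
#' imagingSimParams(10, preset = "tormogen_ca")
#' @export
imagingSimParams <- function(nCells, preset = "",
                             responderFraction = NULL,
                             transientAmplitude = NULL,
                             riseTau = 40, decayTau = 240,
                             baselineLevel = 100, backgroundLevel = 10,
                             bleachRate = 0, noiseSd = 2,
                             frameInterval = 5, nFrames = 180L,
                             events = stimulusEvents("VUAA1", 300, 0, "odor")) {
  if (nzchar(preset)) {
    p <- .IMAGING_PRESETS[[preset]]
    if (is.null(p)) stop("unknown imaging preset: ", preset)
    if (is.null(responderFraction)) responderFraction <- p$responderFraction
    if (is.null(transientAmplitude)) transientAmplitude <- p$sign * p$amplitude
  } else {
    if (is.null(responderFraction)) responderFraction <- 1
    if (is.null(transientAmplitude)) transientAmplitude <- 30
  }
  new("ImagingSimParams",
      nCells = as.integer(nCells), responderFraction = responderFraction,
      transientAmplitude = transientAmplitude,
      riseTau = riseTau, decayTau = decayTau,
      baselineLevel = baselineLevel, backgroundLevel = backgroundLevel,
      bleachRate = bleachRate, noiseSd = noiseSd,
      frameInterval = frameInterval, nFrames = as.integer(nFrames),
      events = events, preset = preset)
}

#' Simulate an imaging recording with known ground truth
#'
#' Each cell is a responder with probability \code{responderFraction}.
#' A responder's trace is
#' background + baseline * (1 - bleachRate)^frame +
#' (amplitude/100 * baseline) * K(t - onset) + Gaussian noise, with K the
#' peak-normalized \code{\link{transientKernel}} summed over all non-"none"
#' events; non-responders carry amplitude 0. The background ROI is a constant
#' offset plus noise. Identical (params, seed) give identical output.
#'
#' @param params an \linkS4class{ImagingSimParams}.
#' @param seed integer.
#' @return A list with \code{recording} (an \linkS4class{ImagingRecording})
#'   and \code{truth}, a data.frame with per-cell \code{roi},
#'   \code{responder} and signed \code{amplitude} (% of baseline).
#' @examples
#' sim <- simulateImagingRecording(imagingSimParams(4, "osn_ca"), seed = 1)
#' sim$truth
#' @export
simulateImagingRecording <- function(params, seed) {
  stopifnot(is(params, "ImagingSimParams"))
  validObject(params)
  withSeed(seed, {
    nF <- params@nFrames
    nC <- params@nCells
    t <- (seq_len(nF) - 1) * params@frameInterval
    responder <- stats::rbinom(nC, 1L, params@responderFraction) == 1L
    amp <- ifelse(responder, params@transientAmplitude, 0)
    bleach <- (1 - params@bleachRate)^(seq_len(nF) - 1)
    sig <- rep(0, nF)
    act <- params@events[params@events$modality != "none", , drop = FALSE]
    for (i in seq_len(nrow(act))) {
      sig <- sig + transientKernel(t - act$onset_time[i],
                                   params@riseTau, params@decayTau)
    }
    cells <- matrix(0, nF, nC)
    for (j in seq_len(nC)) {
      cells[, j] <- params@backgroundLevel +
        params@baselineLevel * bleach +
        (amp[j] / 100) * params@baselineLevel * sig +
        stats::rnorm(nF, 0, params@noiseSd)
    }
    bg <- params@backgroundLevel + stats::rnorm(nF, 0, params@noiseSd)
    roiNames <- sprintf("roi%02d", seq_len(nC))
    m <- cbind(bg, cells)
    colnames(m) <- c("bg", roiNames)
    rec <- imagingRecording(m, frameInterval = params@frameInterval,
                            backgroundRoi = "bg", events = params@events,
                            meta = list(preset = params@preset,
                                        simulated = TRUE))
    list(recording = rec,
         truth = data.frame(roi = roiNames, responder = responder,
                            amplitude = amp, stringsAsFactors = FALSE))
  })
}

#' Transient amplitude as a function of bath concentration
#'
#' A saturating decay amp(c) = amp0 * c50 / (c50 + c): the response magnitude
#' shrinks as the ambient concentration rises, as observed for intracellular
#' potassium responses at increasing extracellular KCl. The sign of
#' \code{amp0} is preserved, so an efflux preset yields negative amplitudes
#' whose magnitude decreases with concentration.
#'
#' @param concentration numeric, mM.
#' @param amp0 numeric, signed amplitude at concentration 0 (% of baseline).
#' @param c50 numeric, half-decay concentration in mM (default 30).
#' @return numeric, signed amplitudes (% of baseline).
#' @export
concentrationAmplitude <- function(concentration, amp0, c50 = 30) {
  stopifnot(all(concentration >= 0), c50 > 0)
  amp0 * c50 / (c50 + concentration)
}
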