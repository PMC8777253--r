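#' Construct an imaging recording
#'
#' @param traces numeric matrix, frames x ROIs, with ROI column names.
#' @param frameInterval numeric, seconds between frames (default 5).
#' @param backgroundRoi character, name of the background ROI column
#'   (default "bg").
#' @param events events data.frame (see \code{\link{stimulusEvents}}).
#' @param meta list of free-form metadata (driver, indicator, genotype, ...).
#' @return An \linkS4class{ImagingRecording}.
#' @examples
#' m <- cbind(bg = rep(2, 6), roi1 = rep(10, 6))
#' rec <- imagingRecording(m, events = stimulusEvents("VUAA1", 10, 0, "odor"))
#' @export
imagingRecording <- function(traces, frameInterval = 5,
                             backgroundRoi = "bg",
                             events = stimulusEvents(character(0), numeric(0)),
                             meta = list()) {
  new("ImagingRecording", traces = traces, frameInterval = frameInterval,
      backgroundRoi = backgroundRoi, events = events, meta = meta)
}

#' Construct a spike train
#'
#' Input times are sorted if needed (with a warning). Duplicate spike times
#' are rejected by default as acquisition artifacts; set
#' \code{allowDuplicates = TRUE} to keep them by shifting each duplicate by a
#' nanosecond (times then remain strictly increasing).
#'
#' @param spikeTimes numeric, seconds from recording start.
#' @param span numeric, recording duration (default 13 s).
#' @param stimulusOnset numeric, seconds (default 3).
#' @param stimulusDuration numeric, seconds (default 0.5).
#' @param treatment,sensillum,neuron,cohort,genotype,fly character labels.
#' @param allowDuplicates logical, see above.
#' @return A \linkS4class{SpikeTrain}.
#' @examples
#' spikeTrain(c(0.1, 0.5, 1.0))
#' @export
spikeTrain <- function(spikeTimes = numeric(0), span = 13,
                       stimulusOnset = 3, stimulusDuration = 0.5,
                       treatment = "no treatment", sensillum = "ab1",
                       neuron = "ab1ABC", cohort = "control",
                       genotype = "", fly = "", allowDuplicates = FALSE) {
  spikeTimes <- as.numeric(spikeTimes)
  if (is.unsorted(spikeTimes)) {
    warning("spike times were not sorted; sorting")
    spikeTimes <- sort(spikeTimes)
  }
  if (anyDuplicated(spikeTimes)) {
    if (!allowDuplicates) {
      stop("duplicate spike times (set allowDuplicates = TRUE to keep them)")
    }
    while (anyDuplicated(spikeTimes)) {
      dup <- duplicated(spikeTimes)
      spikeTimes[dup] <- spikeTimes[dup] + 1e-9
      spikeTimes <- sort(spikeTimes)
    }
  }
  new("SpikeTrain", spikeTimes = spikeTimes, span = span,
      stimulusOnset = stimulusOnset, stimulusDuration = stimulusDuration,
      treatment = treatment, sensillum = sensillum, neuron = neuron,
      cohort = cohort, genotype = genotype, fly = fly)
}

.frequencyTrace <- function(times, rate, binWidth, stage, labels) {
  new("FrequencyTrace", times = as.numeric(times), rate = as.numeric(rate),
      binWidth = binWidth, stage = stage, labels = labels)
}

#' @name accessors
#' @title Accessors for sensilphys data classes
#' @description Slot accessors: the fluorescence matrix, frame times, ROI
#'   names and events of an \linkS4class{ImagingRecording}; the dF/F0 matrix
#'   and baseline window of a \linkS4class{DffTraces}; spike times, span and
#'   onset of a \linkS4class{SpikeTrain}; and the bin grid, rates, stage and
#'   labels of a \linkS4class{FrequencyTrace}.
#' @param x the object.
#' @return The slot value; \code{frameTimes} returns seconds from recording
#'   start (frame 1 at time 0).
NULL

#' @rdname accessors
#' @export
setMethod("traceMatrix", "ImagingRecording", function(x) x@traces)

#' @rdname accessors
#' @export
setMethod("frameTimes", "ImagingRecording", function(x) {
  (seq_len(nrow(x@traces)) - 1) * x@frameInterval
})

#' @rdname accessors
#' @export
setMethod("frameTimes", "DffTraces", function(x) {
  (seq_len(nrow(x@dff)) - 1) * x@frameInterval
})

#' @rdname accessors
#' @export
setMethod("backgroundRoi", "ImagingRecording", function(x) x@backgroundRoi)

#' @rdname accessors
#' @export
setMethod("cellRois", "ImagingRecording", function(x) {
  setdiff(colnames(x@traces), x@backgroundRoi)
})

#' @rdname accessors
#' @export
setMethod("stimulusEventsOf", "ImagingRecording", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("stimulusEventsOf", "DffTraces", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("nFrames", "ImagingRecording", function(x) nrow(x@traces))

#' @rdname accessors
#' @export
setMethod("dffMatrix", "DffTraces", function(x) x@dff)

#' @rdname accessors
#' @export
setMethod("f0Window", "DffTraces", function(x) x@f0Window)

#' @rdname accessors
#' @export
setMethod("f0Values", "DffTraces", function(x) x@f0Values)

#' @rdname accessors
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x) x@spikeTimes)

#' @rdname accessors
#' @export
setMethod("nSpikes", "SpikeTrain", function(x) length(x@spikeTimes))

#' @rdname accessors
#' @export
setMethod("recordingSpan", "SpikeTrain", function(x) x@span)

#' @rdname accessors
#' @export
setMethod("stimulusOnset", "SpikeTrain", function(x) x@stimulusOnset)

#' @rdname accessors
#' @export
setMethod("binTimes", "FrequencyTrace", function(x) x@times)

#' @rdname accessors
#' @export
setMethod("binRate", "FrequencyTrace", function(x) x@rate)

#' @rdname accessors
#' @export
setMethod("binWidth", "FrequencyTrace", function(x) x@binWidth)

#' @rdname accessors
#' @export
setMethod("traceStage", "FrequencyTrace", function(x) x@stage)

#' @rdname accessors
#' @export
setMethod("traceLabels", "FrequencyTrace", function(x) x@labels)

setMethod("show", "ImagingRecording", function(object) {
  cat(sprintf("ImagingRecording: %d frames x %d ROIs (+ background '%s')\n",
              nrow(object@traces), length(cellRois(object)),
              object@backgroundRoi))
  cat(sprintf("  frame interval %g s, span %g s, %d stimulus event(s)\n",
              object@frameInterval,
              nrow(object@traces) * object@frameInterval,
              nrow(object@events)))
  if (nrow(object@events)) {
    cat(sprintf("  events: %s\n",
                paste(sprintf("%s@%gs", object@events$label,
                              object@events$onset_time), collapse = ", ")))
  }
})

setMethod("show", "DffTraces", function(object) {
  cat(sprintf("DffTraces: %d frames x %d cell ROIs (percent dF/F0)\n",
              nrow(object@dff), ncol(object@dff)))
  cat(sprintf("  F0 window: frames %d-%d\n",
              min(object@f0Window), max(object@f0Window)))
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain: %d spikes over %g s (stimulus at %g s)\n",
              length(object@spikeTimes), object@span, object@stimulusOnset))
  cat(sprintf("  %s / %s / %s / %s cohort\n", object@sensillum,
              object@neuron, object@treatment, object@cohort))
})

setMethod("show", "FrequencyTrace", function(object) {
  cat(sprintf("FrequencyTrace (%s): %d bins of %g s, t in [%.3f, %.3f] s\n",
              object@stage, length(object@times), object@binWidth,
              if (length(object@times)) min(object@times) else NA,
              if (length(object@times)) max(object@times) else NA))
})
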