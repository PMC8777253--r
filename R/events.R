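#' Construct a stimulus-event schedule
#'
#' Events are stored as a data.frame with one row per stimulus: a free-text
#' label (e.g. "VUAA1", "DMSO", "air gust", "hexane", "no treatment"), the
#' onset time in seconds from recording start, the duration in seconds
#' (SSR stimuli default to 0.5 s) and the modality.
#'
#' @param label character vector of stimulus labels.
#' @param onset_time numeric vector, seconds from recording start.
#' @param duration numeric vector, seconds.
#' @param modality character vector, each one of "odor", "solvent",
#'   "mechanical", "none".
#' @return A validated events data.frame.
#' @examples
#' stimulusEvents("VUAA1", 300, 0, "odor")
#' @export
stimulusEvents <- function(label, onset_time, duration = 0, modality = "odor") {
  ev <- data.frame(label = as.character(label),
                   onset_time = as.numeric(onset_time),
                   duration = as.numeric(rep_len(duration, length(label))),
                   modality = as.character(rep_len(modality, length(label))),
                   stringsAsFactors = FALSE)
  validateEvents(ev)
  ev
}

#' Validate a stimulus-event schedule
#'
#' @param events events data.frame.
#' @param span optional recording span in seconds; when given, every event
#'   must satisfy onset_time + duration <= span.
#' @return \code{events}, invisibly; errors on violation.
#' @export
validateEvents <- function(events, span = NULL) {
  need <- c("label", "onset_time", "duration", "modality")
  if (!is.data.frame(events) || !all(need %in% names(events))) {
    stop("events must be a data.frame with columns ",
         paste(need, collapse = ", "))
  }
  if (nrow(events)) {
    if (any(!is.finite(events$onset_time)) || any(events$onset_time < 0)) {
      stop("event onset_time must be finite and >= 0")
    }
    if (any(!is.finite(events$duration)) || any(events$duration < 0)) {
      stop("event duration must be finite and >= 0")
    }
    bad <- !events$modality %in% .MODALITIES
    if (any(bad)) {
      stop("unknown event modality: ",
           paste(unique(events$modality[bad]), collapse = ", "))
    }
    if (!is.null(span)) {
      out <- events$onset_time + events$duration > span + 1e-9
      if (any(out)) {
        stop(sprintf("event '%s' at %g s lies outside the %g s recording span",
                     events$label[which(out)[1]],
                     events$onset_time[which(out)[1]], span))
      }
    }
  }
  invisible(events)
}

#' First stimulus onset of a schedule
#' @param events events data.frame.
#' @return numeric, seconds; \code{Inf} when the schedule is empty or all
#'   events have modality "none".
#' @export
firstStimulusOnset <- function(events) {
  validateEvents(events)
  act <- events[events$modality != "none", , drop = FALSE]
  if (!nrow(act)) return(Inf)
  min(act$onset_time)
}
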