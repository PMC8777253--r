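#' Write an imaging recording to CSV + JSON
#'
#' Writes the fluorescence matrix as a plain CSV (`frame` index column, one
#' column per ROI, the background ROI under its own name) and a JSON sidecar
#' holding the frame interval, background ROI name, metadata and the stimulus
#' events. Numeric values are written with 17 significant digits so that a
#' write/read round trip is bit-exact for finite doubles.
#'
#' @param rec an \linkS4class{ImagingRecording}.
#' @param path CSV output path.
#' @param eventsPath JSON sidecar path; defaults to \code{path} with the
#'   extension replaced by \code{.events.json}.
#' @return \code{path}, invisibly.
#' @export
writeImagingRecording <- function(rec, path,
                                  eventsPath = .sidecarPath(path)) {
  stopifnot(is(rec, "ImagingRecording"))
  m <- rec@traces
  chr <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  out <- cbind(frame = as.character(seq_len(nrow(m)) - 1L), chr)
  colnames(out) <- c("frame", colnames(m))
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  side <- list(frame_interval = rec@frameInterval,
               background_roi = rec@backgroundRoi,
               meta = rec@meta,
               events = rec@events)
  jsonlite::write_json(side, eventsPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

.sidecarPath <- function(path) sub("\\.[^.]+$", ".events.json", path)

#' Read an imaging recording from CSV + JSON
#'
#' Inverse of \code{\link{writeImagingRecording}}. The CSV must carry a header
#' row naming the ROIs and the JSON sidecar must name the background ROI; any
#' non-numeric cell is reported with its row and column.
#'
#' @param path CSV path.
#' @param eventsPath JSON sidecar path (default derived from \code{path}).
#' @return An \linkS4class{ImagingRecording}.
#' @export
readImagingRecording <- function(path, eventsPath = .sidecarPath(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(eventsPath)) stop("no event sidecar: ", eventsPath)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!"frame" %in% names(raw)) stop("recording CSV must have a 'frame' column")
  rois <- setdiff(names(raw), "frame")
  m <- matrix(NA_real_, nrow = nrow(raw), ncol = length(rois),
              dimnames = list(NULL, rois))
  for (j in seq_along(rois)) {
    v <- suppressWarnings(as.numeric(raw[[rois[j]]]))
    bad <- which(is.na(v) & !raw[[rois[j]]] %in% c("NA", ""))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   raw[[rois[j]]][bad[1]], bad[1], rois[j]))
    }
    m[, j] <- v
  }
  side <- jsonlite::read_json(eventsPath, simplifyVector = TRUE)
  if (is.null(side$background_roi)) stop("sidecar lacks background_roi")
  if (!side$background_roi %in% rois) {
    stop(sprintf("background ROI '%s' not among CSV columns", side$background_roi))
  }
  ev <- side$events
  if (is.null(ev) || length(ev) == 0 || NROW(ev) == 0) {
    ev <- stimulusEvents(character(0), numeric(0))
  } else {
    ev <- as.data.frame(ev, stringsAsFactors = FALSE)
  }
  imagingRecording(m, frameInterval = side$frame_interval,
                   backgroundRoi = side$background_roi,
                   events = ev,
                   meta = if (is.null(side$meta)) list() else as.list(side$meta))
}

#' Write a spike train to CSV
#'
#' One row per spike with a `time_s` column plus the recording metadata
#' repeated on every row. An empty train is written as a single row with an
#' empty `time_s` so the metadata survive the round trip.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param path CSV output path.
#' @return \code{path}, invisibly.
#' @export
writeSpikeTrain <- function(train, path) {
  stopifnot(is(train, "SpikeTrain"))
  n <- max(1L, length(train@spikeTimes))
  times <- if (length(train@spikeTimes)) {
    sprintf("%.17g", train@spikeTimes)
  } else ""
  df <- data.frame(time_s = times,
                   span = sprintf("%.17g", rep(train@span, n)),
                   stimulus_onset = sprintf("%.17g", rep(train@stimulusOnset, n)),
                   stimulus_duration = sprintf("%.17g", rep(train@stimulusDuration, n)),
                   treatment = rep(train@treatment, n),
                   sensillum = rep(train@sensillum, n),
                   neuron = rep(train@neuron, n),
                   cohort = rep(train@cohort, n),
                   genotype = rep(train@genotype, n),
                   fly = rep(train@fly, n),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a spike train from CSV
#'
#' Inverse of \code{\link{writeSpikeTrain}}. Negative times are rejected;
#' unsorted times are sorted with a warning.
#'
#' @param path CSV path.
#' @param allowDuplicates logical, passed to \code{\link{spikeTrain}}.
#' @return A \linkS4class{SpikeTrain}.
#' @export
readSpikeTrain <- function(path, allowDuplicates = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(df)) stop("spike CSV must have a 'time_s' column")
  times <- suppressWarnings(as.numeric(df$time_s))
  times <- times[!is.na(times)]
  if (any(times < 0)) stop("negative spike time in ", path)
  meta1 <- function(col, default) {
    if (col %in% names(df) && nrow(df)) as.character(df[[col]][1]) else default
  }
  num1 <- function(col, default) {
    if (col %in% names(df) && nrow(df)) as.numeric(df[[col]][1]) else default
  }
  spikeTrain(times,
             span = num1("span", 13),
             stimulusOnset = num1("stimulus_onset", 3),
             stimulusDuration = num1("stimulus_duration", 0.5),
             treatment = meta1("treatment", "no treatment"),
             sensillum = meta1("sensillum", "ab1"),
             neuron = meta1("neuron", "ab1ABC"),
             cohort = meta1("cohort", "control"),
             genotype = meta1("genotype", ""),
             fly = meta1("fly", ""),
             allowDuplicates = allowDuplicates)
}
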