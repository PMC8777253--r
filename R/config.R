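#' Build an analysis configuration
#'
#' Central store for the pipeline's fixed constants. Defaults reproduce the
#' standard protocol: a 10-frame (50 s) baseline window ending one frame
#' before the first stimulation, 25 ms spike bins, a 400 ms rolling average,
#' response windows of 0 to 1 s post-onset (raw and gust-corrected traces)
#' and -0.5 to 1 s (smoothed traces), and a responder threshold of 5 baseline
#' standard deviations.
#'
#' @param f0Frames integer, frames in the baseline window.
#' @param f0Gap integer, frames between baseline window end and the first
#'   stimulus frame.
#' @param binWidth numeric, seconds.
#' @param smoothWindow numeric, seconds; integer multiple of \code{binWidth}.
#' @param responseWindowRaw,responseWindowSmoothed numeric(2), seconds
#'   relative to stimulus onset.
#' @param responderK numeric, responder threshold in baseline SDs.
#' @param consistencyTol numeric, resting-activity agreement tolerance in
#'   pooled Poisson standard errors.
#' @param rngSeed integer, default simulation seed.
#' @return An \linkS4class{AnalysisConfig}.
#' @examples
#' cfg <- analysisConfig()
#' cfg
#' @export
analysisConfig <- function(f0Frames = 10L, f0Gap = 1L,
                           binWidth = 0.025, smoothWindow = 0.400,
                           responseWindowRaw = c(0, 1),
                           responseWindowSmoothed = c(-0.5, 1),
                           responderK = 5, consistencyTol = 2,
                           rngSeed = 1L) {
  new("AnalysisConfig",
      f0Frames = as.integer(f0Frames), f0Gap = as.integer(f0Gap),
      binWidth = binWidth, smoothWindow = smoothWindow,
      responseWindowRaw = as.numeric(responseWindowRaw),
      responseWindowSmoothed = as.numeric(responseWindowSmoothed),
      responderK = responderK, consistencyTol = consistencyTol,
      rngSeed = as.integer(rngSeed))
}

#' Read an analysis configuration from YAML
#'
#' Keys mirror the arguments of \code{\link{analysisConfig}}; absent keys keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return An \linkS4class{AnalysisConfig}.
#' @export
readConfig <- function(path) {
  stopifnot(file.exists(path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysisConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  do.call(analysisConfig, vals)
}

#' Write an analysis configuration to YAML
#'
#' @param config an \linkS4class{AnalysisConfig}.
#' @param path output YAML file path.
#' @return \code{path}, invisibly.
#' @export
writeConfig <- function(config, path) {
  stopifnot(is(config, "AnalysisConfig"))
  vals <- list(
    f0Frames = config@f0Frames, f0Gap = config@f0Gap,
    binWidth = config@binWidth, smoothWindow = config@smoothWindow,
    responseWindowRaw = config@responseWindowRaw,
    responseWindowSmoothed = config@responseWindowSmoothed,
    responderK = config@responderK, consistencyTol = config@consistencyTol,
    rngSeed = config@rngSeed)
  yaml::write_yaml(vals, path)
  invisible(path)
}

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig\n")
  cat(sprintf("  F0 window: %d frames, gap %d frame(s) before first stimulus\n",
              object@f0Frames, object@f0Gap))
  cat(sprintf("  bins: %.3f s, rolling average: %.3f s (%d bins)\n",
              object@binWidth, object@smoothWindow,
              as.integer(round(object@smoothWindow / object@binWidth))))
  cat(sprintf("  response windows: raw [%g, %g] s, smoothed [%g, %g] s\n",
              object@responseWindowRaw[1], object@responseWindowRaw[2],
              object@responseWindowSmoothed[1], object@responseWindowSmoothed[2]))
  cat(sprintf("  responder threshold: %g baseline SDs\n", object@responderK))
})
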