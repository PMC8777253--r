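#' Peak-normalized alpha-function kernel
#'
#' (t/tau) * exp(1 - t/tau) for t >= 0, zero before; peaks at exactly 1 when
#' t = tau and has decayed below 5% of peak by about 4.7 tau, so tau = 0.1 s
#' gives a response lasting roughly half a second.
#'
#' @param t numeric, seconds since stimulus onset.
#' @param tau numeric, seconds.
#' @return numeric kernel values in [0, 1].
#' @export
alphaKernel <- function(t, tau) {
  stopifnot(tau > 0)
  ifelse(t < 0, 0, (t / tau) * exp(1 - t / tau))
}

#' Build spike-train simulation parameters
#'
#' Defaults model a 13 s recording (3 s pre-, 10 s post-stimulus) with a
#' 0.5 s stimulus, a spontaneous rate of 8 spikes/s, an odor response peaking
#' at 120 spikes/s (alpha kernel, tau 0.1 s) and a briefer mechanical (gust)
#' response (tau 0.05 s) whose gain is 20 spikes/s in control flies and
#' 70 spikes/s in the heatshock (thecogen-ablated) cohort.
#'
#' @param baselineRate,odorGain,odorTau,mechGain,mechGainHeatshock,mechTau,span,stimulusOnset,stimulusDuration
#'   see \linkS4class{SpikeSimParams}.
#' @return A \linkS4class{SpikeSimParams}.
#' @export
spikeSimParams <- function(baselineRate = 8, odorGain = 120, odorTau = 0.1,
                           mechGain = 20, mechGainHeatshock = 70,
                           mechTau = 0.05, span = 13, stimulusOnset = 3,
                           stimulusDuration = 0.5) {
  new("SpikeSimParams", baselineRate = baselineRate, odorGain = odorGain,
      odorTau = odorTau, mechGain = mechGain,
      mechGainHeatshock = mechGainHeatshock, mechTau = mechTau,
      span = span, stimulusOnset = stimulusOnset,
      stimulusDuration = stimulusDuration)
}

#' Instantaneous firing rate of the simulation model
#'
#' lambda(t) = baselineRate + odorGain * A(t - onset) + gMech * M(t - onset),
#' with A and M the odor and mechanical \code{\link{alphaKernel}}s and gMech
#' selected by cohort.
#'
#' @param t numeric, seconds from recording start.
#' @param params a \linkS4class{SpikeSimParams}.
#' @param cohort "control" or "heatshock".
#' @return numeric, spikes/s.
#' @export
spikeRate <- function(t, params, cohort = "control") {
  g <- .mechGainFor(params, cohort)
  rel <- t - params@stimulusOnset
  params@baselineRate +
    params@odorGain * alphaKernel(rel, params@odorTau) +
    g * alphaKernel(rel, params@mechTau)
}

.mechGainFor <- function(params, cohort) {
  switch(cohort,
         control = params@mechGain,
         heatshock = params@mechGainHeatshock,
         stop("cohort must be 'control' or 'heatshock'"))
}

#' Simulate a spike train by Poisson thinning
#'
#' Draws an inhomogeneous Poisson process with rate \code{\link{spikeRate}}
#' by rejection (thinning) against the rate's upper bound
#' baselineRate + odorGain + gMech: homogeneous candidates at the bound are
#' kept with probability lambda(t)/bound. Reproducible under a fixed seed.
#'
#' @param params a \linkS4class{SpikeSimParams}.
#' @param seed integer.
#' @param cohort "control" or "heatshock".
#' @param treatment,sensillum,neuron,genotype,fly labels for the train.
#' @return A \linkS4class{SpikeTrain}.
#' @examples
#' simulateSpikeTrain(spikeSimParams(), seed = 1)
#' @export
simulateSpikeTrain <- function(params, seed, cohort = "control",
                               treatment = "odor", sensillum = "ab1",
                               neuron = "ab1ABC", genotype = "", fly = "") {
  stopifnot(is(params, "SpikeSimParams"))
  validObject(params)
  g <- .mechGainFor(params, cohort)
  lmax <- params@baselineRate + params@odorGain + g
  withSeed(seed, {
    times <- numeric(0)
    if (lmax > 0) {
      nCand <- stats::rpois(1, lmax * params@span)
      cand <- sort(stats::runif(nCand, 0, params@span))
      keep <- stats::runif(nCand) <= spikeRate(cand, params, cohort) / lmax
      times <- unique(cand[keep])
    }
    spikeTrain(times, span = params@span,
               stimulusOnset = params@stimulusOnset,
               stimulusDuration = params@stimulusDuration,
               treatment = treatment, sensillum = sensillum, neuron = neuron,
               cohort = cohort, genotype = genotype, fly = fly)
  })
}

# The 16-treatment panel: no treatment, a blank air gust, and 14 odorant
# presentations (the solvent hexane among them). Only five odorants are the
# panel's diagnostic ligands; the remaining labels are synthetic fillers for
# a complete design. Every presented stimulus (odorant or gust) carries the
# mechanical component of the delivery airstream.
.TREATMENT_PANEL <- c(
  "no treatment", "air gust", "hexane",
  "ethyl acetate", "ethyl lactate", "CO2", "methyl acetate",
  "ethyl hexanoate", "ethyl butyrate", "1-hexanol", "2,3-butanedione",
  "pentyl acetate", "1-octen-3-ol", "benzaldehyde", "2-heptanone", "geosmin")

.DIAGNOSTIC_ODORS <- list(
  ab1 = c("ethyl acetate", "ethyl lactate", "CO2"),
  ab2 = "methyl acetate",
  ab3 = "ethyl hexanoate")

.NEURON_FOR <- c(ab1 = "ab1ABC", ab2 = "ab2A", ab3 = "ab3A")

#' The default 16-treatment panel
#' @return character vector of the 16 treatment labels.
#' @export
treatmentPanel <- function() .TREATMENT_PANEL

#' Odor/mechanical gain multipliers for one treatment
#'
#' "no treatment" has neither component; "air gust" and the solvent are
#' mechanical-only; a sensillum's diagnostic odorants drive the full odor
#' gain, other odorants a weak (0.2x) off-target response; all presented
#' stimuli carry the full mechanical component.
#'
#' @param treatment treatment label.
#' @param sensillum sensillum label ("ab1", "ab2", "ab3").
#' @return list with \code{odor} and \code{mech} multipliers and the
#'   \code{modality} of the event.
#' @export
treatmentGains <- function(treatment, sensillum) {
  if (!treatment %in% .TREATMENT_PANEL) {
    stop("unknown treatment label: ", treatment)
  }
  if (treatment == "no treatment") {
    return(list(odor = 0, mech = 0, modality = "none"))
  }
  if (treatment == "air gust") {
    return(list(odor = 0, mech = 1, modality = "mechanical"))
  }
  if (treatment == "hexane") {
    return(list(odor = 0, mech = 1, modality = "solvent"))
  }
  diag <- .DIAGNOSTIC_ODORS[[sensillum]]
  odor <- if (!is.null(diag) && treatment %in% diag) 1 else 0.2
  list(odor = odor, mech = 1, modality = "odor")
}

#' Default experimental design table
#'
#' One row per (sensillum, treatment, cohort) cell: three basiconic sensilla,
#' the 16-treatment panel and both heatshock conditions.
#'
#' @param nFlies integer, flies per cell (default 9).
#' @param sensilla character vector (default ab1, ab2, ab3).
#' @param cohorts character vector (default control, heatshock).
#' @return data.frame with columns sensillum, treatment, cohort, n_flies.
#' @export
defaultDesign <- function(nFlies = 9L, sensilla = c("ab1", "ab2", "ab3"),
                          cohorts = c("control", "heatshock")) {
  d <- expand.grid(treatment = .TREATMENT_PANEL, sensillum = sensilla,
                   cohort = cohorts, stringsAsFactors = FALSE)
  d$n_flies <- as.integer(nFlies)
  d[, c("sensillum", "treatment", "cohort", "n_flies")]
}

#' Simulate a full cohort of spike trains from a design table
#'
#' One train per fly and design row, with per-train seeds derived
#' deterministically from the master seed so any subset is reproducible.
#' Treatment labels select the odor/mechanical gain multipliers via
#' \code{\link{treatmentGains}}; the cohort selects the mechanical gain.
#' Flies are labelled fly01..flyN within each (sensillum, cohort) so the
#' per-fly resting-activity estimators can group the 16 treatments.
#'
#' @param design data.frame with columns sensillum, treatment, cohort,
#'   n_flies (see \code{\link{defaultDesign}}).
#' @param params base \linkS4class{SpikeSimParams}; per-treatment gains are
#'   its \code{odorGain}/\code{mechGain*} scaled by the treatment multipliers.
#' @param seed integer master seed.
#' @return list of \linkS4class{SpikeTrain}.
#' @examples
#' d <- defaultDesign(nFlies = 2, sensilla = "ab2")
#' length(simulateCohort(d, spikeSimParams(), seed = 1))
#' @export
simulateCohort <- function(design, params = spikeSimParams(), seed = 1L) {
  need <- c("sensillum", "treatment", "cohort", "n_flies")
  if (!is.data.frame(design) || !all(need %in% names(design))) {
    stop("design must have columns ", paste(need, collapse = ", "))
  }
  bad <- !design$treatment %in% .TREATMENT_PANEL
  if (any(bad)) {
    stop("unknown treatment label(s): ",
         paste(unique(design$treatment[bad]), collapse = ", "))
  }
  total <- sum(design$n_flies)
  seeds <- deriveSeeds(seed, total)
  trains <- vector("list", total)
  idx <- 0L
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    g <- treatmentGains(row$treatment, row$sensillum)
    p <- params
    p@odorGain <- params@odorGain * g$odor
    p@mechGain <- params@mechGain * g$mech
    p@mechGainHeatshock <- params@mechGainHeatshock * g$mech
    if (g$modality == "none") p@stimulusDuration <- 0
    neuron <- if (row$sensillum %in% names(.NEURON_FOR)) {
      .NEURON_FOR[[row$sensillum]]
    } else row$sensillum
    for (f in seq_len(row$n_flies)) {
      idx <- idx + 1L
      trains[[idx]] <- simulateSpikeTrain(
        p, seed = seeds[idx], cohort = row$cohort,
        treatment = row$treatment, sensillum = row$sensillum,
        neuron = neuron, fly = sprintf("fly%02d", f))
    }
  }
  trains
}
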