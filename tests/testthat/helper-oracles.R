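# Independent oracles kept deliberately naive: these re-derive the same
# quantities as the package by enumeration or refinement and must never call
# the code paths they check.

# Half-open [a, b) spike count by explicit enumeration.
bruteCount <- function(times, a, b) {
  n <- 0L
  for (t in times) if (t >= a && t < b) n <- n + 1L
  n
}

# Centered full-window rolling mean by an explicit loop.
slidingMean <- function(x, k) {
  n <- length(x) - k + 1L
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- mean(x[i:(i + k - 1L)])
  out
}

# Riemann sum of the linear interpolant of (x, y) on a refined grid.
refinedRiemann <- function(x, y, refine = 100L) {
  xs <- seq(min(x), max(x), length.out = (length(x) - 1L) * refine + 1L)
  ys <- approx(x, y, xout = xs)$y
  dx <- diff(xs)
  sum((ys[-1] + ys[-length(ys)]) / 2 * dx)
}

# Inhomogeneous-Poisson simulator by time rescaling: invert the cumulative
# intensity of unit-rate exponential arrivals on a fine grid.
timeRescalingTrain <- function(rateFun, span, dt = 1e-3) {
  grid <- seq(0, span, by = dt)
  lam <- rateFun(grid)
  Lam <- c(0, cumsum((lam[-1] + lam[-length(lam)]) / 2 * dt))
  total <- Lam[length(Lam)]
  s <- cumsum(rexp(ceiling(total + 10 * sqrt(total) + 10)))
  s <- s[s <= total]
  approx(Lam, grid, xout = s, ties = "ordered")$y
}

# A quick simulated recording + truth used across tests.
makeImagingSim <- function(nCells = 20, preset = "tormogen_ca", seed = 11,
                           ...) {
  simulateImagingRecording(imagingSimParams(nCells, preset, ...), seed = seed)
}
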