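#' Steady-state mRNA level
#'
#' For `dM/dt = tr - kd * M`, the steady state is `M* = tr / kd` — the
#' relation underlying steady-state half-life inference (`M/TR = 1/kd`).
#'
#' @param tr transcription rate (a.u./min), `>= 0`.
#' @param kd decay rate (1/min), `> 0`.
#' @return `tr / kd`.
#' @examples
#' steadyState(10, 2)
#' @export
steadyState <- function(tr, kd) {
  if (any(kd <= 0)) stop("kd must be > 0")
  tr / kd
}

#' Simulate the mRNA-level response to a transcription-rate schedule
#'
#' Solves `dM/dt = TR(t) - kd * M` for a piecewise-constant TR schedule in
#' closed form per segment: within a segment with steady state
#' `M* = TR/kd`, `M(t) = M* + (M_start - M*) * exp(-kd * dt)`. The
#' trajectory relaxes monotonically toward each segment's steady state (no
#' overshoot within a segment); a pulse in TR produces a peak whose timing
#' is set by `kd` — faster turnover, faster response.
#'
#' @param model a [KineticModel].
#' @param tGrid increasing time grid starting at 0 (minutes).
#' @return A data.frame with columns `t` and `M`.
#' @examples
#' m <- KineticModel(trTimes = c(0, 10), trValues = c(1, 2), kd = 0.1,
#'                   M0 = 10)
#' head(simulateResponse(m, seq(0, 60, by = 5)))
#' @export
simulateResponse <- function(model, tGrid) {
  stopifnot(is(model, "KineticModel"))
  if (length(tGrid) < 1 || tGrid[1] < 0 || is.unsorted(tGrid, strictly = TRUE))
    stop("tGrid must be strictly increasing and start at t >= 0")
  starts <- model@trTimes
  mstar <- model@trValues / model@kd
  # mRNA level at each segment start, chained through the closed form
  mAtStart <- numeric(length(starts))
  mAtStart[1] <- model@M0
  if (length(starts) > 1) {
    for (i in seq_len(length(starts) - 1)) {
      dt <- starts[i + 1] - starts[i]
      mAtStart[i + 1] <- mstar[i] + (mAtStart[i] - mstar[i]) *
        exp(-model@kd * dt)
    }
  }
  seg <- findInterval(tGrid, starts)
  M <- mstar[seg] + (mAtStart[seg] - mstar[seg]) *
    exp(-model@kd * (tGrid - starts[seg]))
  data.frame(t = tGrid, M = M)
}

#' Relaxation half-time of the mRNA response
#'
#' The time for the mRNA level to cover half the gap to its new steady
#' state after a step change in TR: `ln(2) / kd`. Doubling the decay rate
#' halves the response time — and if TR and kd are scaled together, the
#' steady state is unchanged while the response accelerates, the
#' buffering-speed trade-off: high turnover buys responsiveness at
#' constant abundance.
#'
#' @param kd decay rate (1/min), `> 0`.
#' @return Half-time in minutes.
#' @examples
#' responseHalftime(0.1)
#' @export
responseHalftime <- function(kd) {
  if (any(kd <= 0)) stop("kd must be > 0")
  log(2) / kd
}
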