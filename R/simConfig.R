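#' @include AllClasses.R
NULL

.DRUG_LEVELS <- c("saline", "muscimol")
.STIM_LEVELS <- c("NoStim", "2Hz", "20Hz")

.condMatrix <- function(x, drugLevels, stimLevels, what) {
  if (is.matrix(x)) {
    if (is.null(dimnames(x))) dimnames(x) <- list(drugLevels, stimLevels)
    return(x)
  }
  if (length(x) == 1L)
    x <- rep(x, length(drugLevels) * length(stimLevels))
  if (length(x) != length(drugLevels) * length(stimLevels))
    stop(what, " must be a scalar or a drug-by-stim matrix")
  matrix(x, nrow = length(drugLevels),
         dimnames = list(drugLevels, stimLevels))
}

#' Construct a simulation configuration
#'
#' Builds a validated \linkS4class{SimConfig} with defaults that emulate the
#' experimental design the analyses assume: 12 animals (6 opsin-expressing
#' and recorded, 6 controls), 60-minute sessions of the FI12 task with ITIs
#' drawn from \{6, 8, 10, 12\} s, one session per drug level (saline,
#' muscimol) and three stimulation conditions (NoStim, 2 Hz, 20 Hz)
#' pseudo-randomly interleaved so per-condition trial counts differ by at
#' most one.
#'
#' Behavioural defaults place mean start times at 8.4 s under saline,
#' 7.8 s under muscimol without stimulation, and 8.8 s under muscimol with
#' 20-Hz stimulation, with a scalar-timing coefficient of variation of 0.15
#' and press rates of 0.1/2 presses/s before/after the start.  Spike-train
#' defaults give half the units a linear time-ramp whose slope is 0.4
#' spikes/s per s under saline, attenuated to 0.15 under muscimol and
#' restored to 0.4 by 20-Hz stimulation.  A third of units are
#' narrow-waveform FSIs; waveform classes are separated by well over five
#' within-class SDs on both features so classification is near-perfect.
#'
#' @param seed integer root seed; every random draw in the generator is
#'   derived from it.
#' @param nAnimals,nOpsin animal counts (opsin animals carry units).
#' @param nSessionsPerCondition sessions per animal per drug level.
#' @param sessionMinutes session duration, minutes.
#' @param interval the fixed interval, seconds.
#' @param itiChoices menu of intertrial intervals, seconds.
#' @param stimLevels,drugLevels condition label sets.
#' @param startMu mean start time, seconds: a scalar or a drug-by-stim
#'   matrix (rows drugs, columns stim levels).
#' @param startCv coefficient of variation of start times.
#' @param animalSd SD of animal-level start-time offsets, seconds.
#' @param startDist "normal" (truncated) or "lognormal".
#' @param rateLow,rateHigh press rates before/after the start, presses/s.
#' @param timeout trial cutoff when no press follows the interval, seconds.
#' @param nUnits number of units across the opsin animals.
#' @param fracRamping proportion of ramping units.
#' @param rampIntercept mean baseline firing rate, spikes/s.
#' @param rampInterceptSd log-scale SD of per-unit baselines (0 = identical).
#' @param rampSlope ramp slope, spikes/s per s: scalar or drug-by-stim matrix.
#' @param fracFsi proportion of narrow-waveform units.
#' @param waveformParams per-class feature distributions, see
#'   \linkS4class{SimConfig}.
#' @param waveformHz waveform sampling rate, Hz.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 1, sessionMinutes = 10, nUnits = 8)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      nAnimals = 12L,
                      nOpsin = 6L,
                      nSessionsPerCondition = 1L,
                      sessionMinutes = 60,
                      interval = 12,
                      itiChoices = c(6, 8, 10, 12),
                      stimLevels = .STIM_LEVELS,
                      drugLevels = .DRUG_LEVELS,
                      startMu = NULL,
                      startCv = 0.15,
                      animalSd = 0.3,
                      startDist = "normal",
                      rateLow = 0.1,
                      rateHigh = 2,
                      timeout = 2 * interval,
                      nUnits = 50L,
                      fracRamping = 0.5,
                      rampIntercept = 3,
                      rampInterceptSd = 0.3,
                      rampSlope = NULL,
                      fracFsi = 1 / 3,
                      waveformParams = NULL,
                      waveformHz = 40000) {
  if (is.null(startMu)) {
    startMu <- matrix(c(8.4, 8.4, 8.4,    # saline: NoStim, 2Hz, 20Hz
                        7.8, 7.9, 8.8),   # muscimol
                      nrow = 2, byrow = TRUE,
                      dimnames = list(drugLevels, stimLevels))
  }
  if (is.null(rampSlope)) {
    rampSlope <- matrix(c(0.4, 0.4, 0.4,
                          0.15, 0.2, 0.4),
                        nrow = 2, byrow = TRUE,
                        dimnames = list(drugLevels, stimLevels))
  }
  if (is.null(waveformParams)) {
    waveformParams <- list(
      MSN = list(p2t_ms = c(0.60, 0.05), hpw_ms = c(0.25, 0.03)),
      FSI = list(p2t_ms = c(0.20, 0.03), hpw_ms = c(0.10, 0.02)))
  }
  new("SimConfig",
      seed = as.integer(seed),
      nAnimals = as.integer(nAnimals),
      nOpsin = as.integer(nOpsin),
      nSessionsPerCondition = as.integer(nSessionsPerCondition),
      sessionMinutes = as.numeric(sessionMinutes),
      interval = as.numeric(interval),
      itiChoices = as.numeric(itiChoices),
      stimLevels = stimLevels,
      drugLevels = drugLevels,
      startMu = .condMatrix(startMu, drugLevels, stimLevels, "startMu"),
      startCv = startCv,
      animalSd = animalSd,
      startDist = startDist,
      rateLow = rateLow,
      rateHigh = rateHigh,
      timeout = timeout,
      nUnits = as.integer(nUnits),
      fracRamping = fracRamping,
      rampIntercept = rampIntercept,
      rampInterceptSd = rampInterceptSd,
      rampSlope = .condMatrix(rampSlope, drugLevels, stimLevels, "rampSlope"),
      fracFsi = fracFsi,
      waveformParams = waveformParams,
      waveformHz = waveformHz)
}

## Derive independent module seeds from the root seed.  Kept below 2^31 so
## they are valid R integer seeds.
.splitSeed <- function(seed, n = 6L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}
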