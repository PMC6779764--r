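#' @include fitime-package.R
NULL

setClassUnion("SimConfigOrNULL", "NULL")

#' Simulation configuration for synthetic FI12 sessions
#'
#' Holds every parameter of the synthetic-session generator: task timing
#' (interval, intertrial intervals, session length), condition design
#' (drug and stimulation levels, trials interleaved in shuffled blocks so
#' per-condition counts differ by at most one), the two-state behavioural
#' response model (per-trial start time drawn from a truncated Normal whose
#' SD scales with its mean — the scalar-timing property — with low/high
#' press rates before/after the start), the spike-train model (ramping
#' units follow an inhomogeneous Poisson process with rate
#' \eqn{\lambda(t) = \max(0, a + b t)} inside the interval), and the
#' waveform classes used for MSN/FSI classification.
#'
#' Use the \code{\link{simConfig}} constructor rather than \code{new()}.
#'
#' @slot seed integer root seed; all randomness flows from it.
#' @slot nAnimals total number of animals (first \code{nOpsin} carry opsin).
#' @slot nOpsin number of opsin-expressing (recorded) animals.
#' @slot nSessionsPerCondition sessions per animal per drug level.
#' @slot sessionMinutes session duration, minutes.
#' @slot interval fixed interval, seconds.
#' @slot itiChoices intertrial-interval menu, seconds.
#' @slot stimLevels,drugLevels condition label sets.
#' @slot startMu drug-by-stim matrix of mean start times, seconds.
#' @slot startCv coefficient of variation of start times (SD = cv * mean).
#' @slot animalSd SD of animal-level start-time offsets, seconds.
#' @slot startDist start-time distribution, "normal" or "lognormal".
#' @slot rateLow,rateHigh press rates before/after the start, presses/s.
#' @slot timeout trial timeout when no post-interval press occurs, seconds.
#' @slot nUnits number of simulated units (across opsin animals).
#' @slot fracRamping proportion of units with a time-ramping rate.
#' @slot rampIntercept baseline firing rate a, spikes/s.
#' @slot rampInterceptSd lognormal SD (log scale) of per-unit baselines.
#' @slot rampSlope drug-by-stim matrix of ramp slopes b, spikes/s per s.
#' @slot fracFsi proportion of narrow-waveform (FSI) units.
#' @slot waveformParams list with elements \code{MSN} and \code{FSI}, each
#'   \code{list(p2t_ms = c(mean, sd), hpw_ms = c(mean, sd))}: peak-to-trough
#'   duration and half-peak width, milliseconds.
#' @slot waveformHz waveform sampling rate, Hz.
#'
#' @seealso \code{\link{simConfig}}, \code{\link{simulateBehavior}},
#'   \code{\link{simulateSpikes}}
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  nAnimals = "integer",
  nOpsin = "integer",
  nSessionsPerCondition = "integer",
  sessionMinutes = "numeric",
  interval = "numeric",
  itiChoices = "numeric",
  stimLevels = "character",
  drugLevels = "character",
  startMu = "matrix",
  startCv = "numeric",
  animalSd = "numeric",
  startDist = "character",
  rateLow = "numeric",
  rateHigh = "numeric",
  timeout = "numeric",
  nUnits = "integer",
  fracRamping = "numeric",
  rampIntercept = "numeric",
  rampInterceptSd = "numeric",
  rampSlope = "matrix",
  fracFsi = "numeric",
  waveformParams = "list",
  waveformHz = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  chk <- function(cond, m) if (!isTRUE(cond)) msg <<- c(msg, m)
  chk(object@interval > 0, "interval must be positive")
  chk(object@sessionMinutes > 0, "sessionMinutes must be positive")
  chk(all(object@itiChoices > 0), "itiChoices must be positive")
  chk(object@rateLow >= 0 && object@rateHigh >= 0,
      "press rates must be non-negative")
  chk(object@rampIntercept >= 0, "rampIntercept must be non-negative")
  chk(object@timeout >= object@interval, "timeout must be >= interval")
  chk(object@startCv >= 0, "startCv must be non-negative")
  chk(object@fracRamping >= 0 && object@fracRamping <= 1,
      "fracRamping must be in [0, 1]")
  chk(object@fracFsi >= 0 && object@fracFsi <= 1, "fracFsi must be in [0, 1]")
  chk(object@nOpsin <= object@nAnimals, "nOpsin cannot exceed nAnimals")
  chk(object@startDist %in% c("normal", "lognormal"),
      "startDist must be 'normal' or 'lognormal'")
  dn <- list(object@drugLevels, object@stimLevels)
  for (nm in c("startMu", "rampSlope")) {
    m <- slot(object, nm)
    chk(identical(dim(m), c(length(dn[[1L]]), length(dn[[2L]]))) &&
          identical(dimnames(m), dn),
        sprintf("%s must be a drug-by-stim matrix with matching dimnames", nm))
  }
  chk(all(object@startMu > 0) && all(object@startMu <= object@interval),
      "startMu values must lie in (0, interval]")
  for (kl in c("MSN", "FSI")) {
    wp <- object@waveformParams[[kl]]
    chk(is.list(wp) && all(c("p2t_ms", "hpw_ms") %in% names(wp)),
        sprintf("waveformParams$%s must define p2t_ms and hpw_ms", kl))
  }
  if (length(msg)) msg else TRUE
})

#' A sorted single unit: spike times plus mean waveform
#'
#' One putative neuron after spike sorting: spike times on the session
#' clock, the mean spike waveform with its sampling rate, and the session
#' mean firing rate.  Synthetic units additionally carry their generative
#' ground truth (baseline rate, per-condition ramp slopes, ramping flag,
#' true waveform class) in \code{truth()} for parameter-recovery tests.
#'
#' @slot unitId,sessionId,animalId identifier labels.
#' @slot spikeTimes sorted spike times, seconds (session clock).
#' @slot waveform mean waveform samples, microvolts.
#' @slot samplingRate waveform sampling rate, Hz.
#' @slot meanRate session mean firing rate, Hz (count / recording span).
#' @slot truth list of generative ground truth (synthetic units only).
#' @export
setClass("SpikeUnit", representation(
  unitId = "character",
  sessionId = "character",
  animalId = "character",
  spikeTimes = "numeric",
  waveform = "numeric",
  samplingRate = "numeric",
  meanRate = "numeric",
  truth = "list"
))

setValidity("SpikeUnit", function(object) {
  msg <- character()
  if (is.unsorted(object@spikeTimes))
    msg <- c(msg, "spikeTimes must be sorted ascending")
  if (length(object@spikeTimes) && any(object@spikeTimes < 0))
    msg <- c(msg, "spikeTimes must be non-negative")
  if (length(object@samplingRate) && object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be positive")
  if (length(msg)) msg else TRUE
})

#' A set of sessions: trial table plus spike units
#'
#' Container for one simulated or loaded experiment: the trial table (one
#' row per trial with condition labels, onset, response times on the trial
#' clock, reward time and ITI) and the list of \linkS4class{SpikeUnit}
#' objects, plus the generating \linkS4class{SimConfig} when the data are
#' synthetic.
#'
#' @slot trials data.frame, see \code{\link{simulateBehavior}} for columns.
#' @slot units list of \linkS4class{SpikeUnit}.
#' @slot config the generating \linkS4class{SimConfig}, or NULL.
#' @export
setClass("FiSession", representation(
  trials = "data.frame",
  units = "list",
  config = "ANY"
))

.TRIAL_COLUMNS <- c("animal_id", "session_id", "trial_index", "drug", "stim",
                    "onset_s", "iti_s", "reward_time_s", "response_times")

setValidity("FiSession", function(object) {
  msg <- character()
  missing <- setdiff(.TRIAL_COLUMNS, names(object@trials))
  if (length(missing))
    msg <- c(msg, paste("trials is missing columns:",
                        paste(missing, collapse = ", ")))
  if (!all(vapply(object@units, is, logical(1), "SpikeUnit")))
    msg <- c(msg, "units must all be SpikeUnit objects")
  if (length(msg)) msg else TRUE
})

#' Curvature of a cumulative response record
#'
#' Result of \code{\link{curvatureIndex}}: a dimensionless scalar in
#' [-1, 1] measuring the deviation of the cumulative response record from
#' the straight line a constant response rate would trace.  Zero indicates
#' a constant rate; positive values indicate responding concentrated late
#' in the interval (temporal control, "scalloped" records); negative values
#' indicate early responding.
#'
#' @slot value the curvature value; NA when undefined (no responses).
#' @slot nSegments number of equal segments (discrete method).
#' @slot method "fry_discrete" or "trapezoid_continuous".
#' @slot totalResponses number of responses entering the record.
#' @slot defined FALSE when the record holds no responses.
#' @export
setClass("CurvatureResult", representation(
  value = "numeric",
  nSegments = "integer",
  method = "character",
  totalResponses = "integer",
  defined = "logical"
))

#' Single-trial start time
#'
#' Result of \code{\link{detectStartTime}}: the estimated moment of the
#' low-to-high transition in response rate within one trial, with the value
#' of the change-point objective at the optimum.
#'
#' @slot start estimated start time, seconds in [0, T].
#' @slot objective value of the rate-contrast objective at the optimum.
#' @slot nResponses number of responses in the trial.
#' @slot valid FALSE when the trial has fewer than the minimum responses.
#' @export
setClass("StartTimeResult", representation(
  start = "numeric",
  objective = "numeric",
  nResponses = "integer",
  valid = "logical"
))

#' Units-by-time PETH matrix
#'
#' A \linkS4class{SummarizedExperiment} whose rows are units and whose
#' columns are time bins across the fixed interval.  Assay \code{"z"} holds
#' the z-scored, Gaussian-smoothed trial-averaged firing used for display;
#' assay \code{"rate"} holds the raw trial-averaged rates (spikes/s).
#' Row metadata records each unit's loading on the first principal
#' component; \code{sortOrder()} gives the row permutation that orders
#' units by that loading (sign fixed so positive loadings are
#' increasing-in-time profiles, putting upward-ramping units at one edge).
#'
#' @slot bin bin width, seconds.
#' @slot bandwidth Gaussian smoothing bandwidth (SD), seconds.
#' @slot sortOrder integer permutation of the rows.
#' @export
setClass("PethMatrix",
         contains = "SummarizedExperiment",
         representation(bin = "numeric",
                        bandwidth = "numeric",
                        sortOrder = "integer"))

setValidity("PethMatrix", function(object) {
  if (length(object@sortOrder) &&
      !identical(sort(object@sortOrder), seq_len(nrow(object))))
    "sortOrder must be a permutation of the row indices"
  else TRUE
})
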