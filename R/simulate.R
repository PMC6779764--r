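#' @include simConfig.R
NULL

## truncated-Normal / lognormal start-time draw, mean mu, cv * mu spread
.drawStart <- function(n, mu, cv, dist) {
  if (cv == 0) return(rep(mu, n))
  if (dist == "lognormal") {
    sdlog <- sqrt(log(1 + cv^2))
    return(stats::rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog))
  }
  s <- rnorm(n, mu, cv * mu)
  bad <- which(s <= 0)
  while (length(bad)) {              # truncate to (0, Inf) by resampling
    s[bad] <- rnorm(length(bad), mu, cv * mu)
    bad <- bad[s[bad] <= 0]
  }
  s
}

## homogeneous Poisson press times on [a, b) at `rate`
.poissonTimes <- function(rate, a, b) {
  if (b <= a || rate <= 0) return(numeric())
  n <- rpois(1L, rate * (b - a))
  sort(runif(n, a, b))
}

#' Simulate FI12 behavioural sessions
#'
#' Generates the trial table of a synthetic experiment under the two-state
#' response model: on each trial the animal presses at \code{rateLow}
#' before its start time and at \code{rateHigh} afterwards, with the start
#' time drawn from a truncated Normal (or lognormal) whose SD is
#' \code{startCv} times its mean (scalar timing).  The trial ends at the
#' first press after the fixed interval (rewarded) or at \code{timeout}
#' when no such press occurs; trials tile the session separated by ITIs
#' drawn uniformly from \code{itiChoices}.  Stimulation labels are assigned
#' by shuffled-block interleaving so per-session condition counts differ by
#' at most one; each animal runs one session per drug level (times
#' \code{nSessionsPerCondition}).  Control (non-opsin) animals receive the
#' laser but not the opsin, so their start times use the first stimulation
#' level (the no-stimulation baseline) regardless of the trial's label.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a data.frame with one row per trial and columns
#'   \code{animal_id}, \code{virus} (ChR2 for opsin animals, mCherry
#'   otherwise), \code{session_id}, \code{trial_index}, \code{drug},
#'   \code{stim}, \code{onset_s} (session clock), \code{iti_s},
#'   \code{reward_time_s} (trial clock; NA on timeout trials),
#'   \code{trial_end_s} (trial clock), \code{true_start_s} (generative
#'   start time, for recovery tests), and the list-column
#'   \code{response_times} (sorted press times on the trial clock).
#' @examples
#' cfg <- simConfig(seed = 2, nAnimals = 2, nOpsin = 1, sessionMinutes = 5)
#' tr <- simulateBehavior(cfg)
#' head(tr[, c("animal_id", "drug", "stim", "true_start_s")])
#' @export
simulateBehavior <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (config@rateHigh <= 0 && config@rateLow <= 0)
    warning("both press rates are zero: every trial will time out")
  set.seed(.splitSeed(config@seed)[1L])
  S <- config@sessionMinutes * 60
  T <- config@interval
  animals <- sprintf("A%02d", seq_len(config@nAnimals))
  offsets <- rnorm(config@nAnimals, 0, config@animalSd)
  rows <- list()
  for (ai in seq_len(config@nAnimals)) {
    for (drug in config@drugLevels) {
      for (rep in seq_len(config@nSessionsPerCondition)) {
        sid <- sprintf("%s_%s_%d", animals[ai], drug, rep)
        onset <- 0
        idx <- 0L
        pool <- character()
        while (onset < S) {
          if (!length(pool)) pool <- sample(config@stimLevels)
          stim <- pool[1L]; pool <- pool[-1L]
          idx <- idx + 1L
          ## stimulation only has behavioural effects in opsin animals;
          ## controls receive the laser but their start times ignore it
          effStim <- if (ai <= config@nOpsin) stim else config@stimLevels[1L]
          mu <- config@startMu[drug, effStim] + offsets[ai]
          mu <- max(mu, 0.5)   # keep animal offsets from driving mu <= 0
          s <- .drawStart(1L, mu, config@startCv, config@startDist)
          lo <- .poissonTimes(config@rateLow, 0, min(s, config@timeout))
          hi <- .poissonTimes(config@rateHigh, min(s, config@timeout),
                              config@timeout)
          presses <- c(lo, hi)
          post <- presses[presses >= T]
          if (length(post)) {
            reward <- post[1L]
            end <- reward
          } else {
            reward <- NA_real_
            end <- config@timeout
          }
          presses <- presses[presses <= end]
          iti <- sample(config@itiChoices, 1L)
          rows[[length(rows) + 1L]] <- list(
            animal_id = animals[ai],
            virus = if (ai <= config@nOpsin) "ChR2" else "mCherry",
            session_id = sid,
            trial_index = idx,
            drug = drug,
            stim = stim,
            onset_s = onset,
            iti_s = iti,
            reward_time_s = reward,
            trial_end_s = end,
            true_start_s = s,
            response_times = presses)
          onset <- onset + end + iti
        }
      }
    }
  }
  out <- data.frame(
    animal_id = vapply(rows, `[[`, character(1), "animal_id"),
    virus = vapply(rows, `[[`, character(1), "virus"),
    session_id = vapply(rows, `[[`, character(1), "session_id"),
    trial_index = vapply(rows, `[[`, integer(1), "trial_index"),
    drug = vapply(rows, `[[`, character(1), "drug"),
    stim = vapply(rows, `[[`, character(1), "stim"),
    onset_s = vapply(rows, `[[`, numeric(1), "onset_s"),
    iti_s = vapply(rows, `[[`, numeric(1), "iti_s"),
    reward_time_s = vapply(rows, `[[`, numeric(1), "reward_time_s"),
    trial_end_s = vapply(rows, `[[`, numeric(1), "trial_end_s"),
    true_start_s = vapply(rows, `[[`, numeric(1), "true_start_s"),
    stringsAsFactors = FALSE)
  out$response_times <- lapply(rows, `[[`, "response_times")
  out
}

#' Simulate mean spike waveforms for two unit classes
#'
#' Draws, for each unit, the two scalar waveform features (peak-to-trough
#' duration and half-peak width, ms) from its class distribution and
#' renders a biphasic difference-of-Gaussians template at the configured
#' sampling rate: a dominant negative trough whose width at half amplitude
#' equals the drawn half-peak width, followed by a smaller positive peak at
#' the drawn peak-to-trough delay.  Only these two scalars matter
#' downstream; the template exists so feature extraction can be exercised
#' on realistic traces.
#'
#' @param config a \linkS4class{SimConfig} (uses \code{waveformParams} and
#'   \code{waveformHz}).
#' @param nUnits number of waveforms to draw.
#' @param klass optional character vector of class labels ("MSN"/"FSI");
#'   when NULL, \code{round(fracFsi * nUnits)} units are FSI, assigned at
#'   random.
#' @return a list with elements \code{waveforms} (list of numeric traces,
#'   microvolts), \code{klass} (true labels), \code{p2t_ms} and
#'   \code{hpw_ms} (designed feature values), \code{samplingRate}, and
#'   \code{warning} (character, non-empty when the two classes overlap to
#'   within two pooled SDs on either feature).
#' @export
simulateWaveforms <- function(config, nUnits = config@nUnits, klass = NULL) {
  stopifnot(is(config, "SimConfig"))
  if (is.null(klass)) {
    nF <- round(config@fracFsi * nUnits)
    klass <- rep("MSN", nUnits)
    if (nF > 0) klass[sample.int(nUnits, nF)] <- "FSI"
  }
  stopifnot(length(klass) == nUnits, all(klass %in% c("MSN", "FSI")))
  wp <- config@waveformParams
  warn <- character()
  for (feat in c("p2t_ms", "hpw_ms")) {
    d <- abs(wp$MSN[[feat]][1L] - wp$FSI[[feat]][1L])
    pooled <- sqrt(mean(c(wp$MSN[[feat]][2L]^2, wp$FSI[[feat]][2L]^2)))
    if (d < 2 * pooled)
      warn <- c(warn, sprintf("classes overlap on %s (separation %.2f SD)",
                              feat, d / pooled))
  }
  dt <- 1000 / config@waveformHz          # sample period, ms
  p2t <- hpw <- numeric(nUnits)
  wf <- vector("list", nUnits)
  for (i in seq_len(nUnits)) {
    p <- wp[[klass[i]]]
    p2t[i] <- max(rnorm(1, p$p2t_ms[1L], p$p2t_ms[2L]), 4 * dt)
    hpw[i] <- max(rnorm(1, p$hpw_ms[1L], p$hpw_ms[2L]), 4 * dt)
    sig1 <- hpw[i] / (2 * sqrt(2 * log(2)))
    sig2 <- 1.6 * sig1
    t0 <- 0.8                              # trough position, ms
    len <- t0 + p2t[i] + 5 * sig2 + 0.5
    tt <- seq(0, len, by = dt)
    wf[[i]] <- -100 * exp(-(tt - t0)^2 / (2 * sig1^2)) +
      40 * exp(-(tt - t0 - p2t[i])^2 / (2 * sig2^2))
  }
  list(waveforms = wf, klass = klass, p2t_ms = p2t, hpw_ms = hpw,
       samplingRate = config@waveformHz, warning = warn)
}

## session firing-rate function for one unit, evaluated at session times tt
.unitLambda <- function(tt, a, bvec, onsets, ends, interval) {
  lam <- rep(a, length(tt))
  j <- findInterval(tt, onsets)
  ok <- j >= 1L
  ok[ok] <- tt[ok] < onsets[j[ok]] + pmin(ends[j[ok]], interval)
  trel <- tt[ok] - onsets[j[ok]]
  lam[ok] <- pmax(0, a + bvec[j[ok]] * trel)
  lam
}

#' Simulate spike trains for striatal units
#'
#' Attaches synthetic units to the opsin animals' sessions, assigning each
#' unit to exactly one session round-robin (sessions are recorded on
#' separate days, so a unit is observed under one drug condition).  Each
#' unit has a per-unit baseline rate \eqn{a} (lognormal around
#' \code{rampIntercept});
#' ramping units (a \code{fracRamping} share) fire as an inhomogeneous
#' Poisson process with \eqn{\lambda(t) = \max(0, a + b t)} across the
#' 12-s interval of every trial, where the slope \eqn{b} depends on the
#' trial's (drug, stim) cell via \code{rampSlope}; outside the interval
#' (ITI, post-reward) and for non-ramping units the rate is the baseline
#' \eqn{a}.  Sampling uses exact Poisson thinning against the peak rate.
#' Each unit carries its generative truth (\code{truth()}): baseline,
#' slope matrix, ramping flag and true waveform class.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param trials trial table from \code{\link{simulateBehavior}}.
#' @return list of \linkS4class{SpikeUnit}.
#' @export
simulateSpikes <- function(config, trials) {
  stopifnot(is(config, "SimConfig"), nrow(trials) > 0)
  ss <- .splitSeed(config@seed)
  set.seed(ss[2L])
  n <- config@nUnits
  opsin <- sprintf("A%02d", seq_len(config@nOpsin))
  opsinSessions <- unique(trials$session_id[trials$animal_id %in% opsin])
  if (!length(opsinSessions))
    stop("no sessions belong to opsin animals; cannot place units")
  unitSession <- opsinSessions[(seq_len(n) - 1L) %% length(opsinSessions) + 1L]
  nRamp <- round(config@fracRamping * n)
  isRamping <- rep(FALSE, n)
  if (nRamp > 0) isRamping[sample.int(n, nRamp)] <- TRUE
  a <- config@rampIntercept *
    exp(rnorm(n, 0, config@rampInterceptSd) - config@rampInterceptSd^2 / 2)
  wfs <- simulateWaveforms(config, n)
  S <- config@sessionMinutes * 60
  bmax <- max(0, max(config@rampSlope))
  units <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- unitSession[i]
    tr <- trials[trials$session_id == sid, ]
    span <- max(S, max(tr$onset_s + tr$trial_end_s))
    bvec <- if (isRamping[i])
      config@rampSlope[cbind(tr$drug, tr$stim)] else rep(0, nrow(tr))
    lamMax <- a[i] + if (isRamping[i]) bmax * config@interval else 0
    st <- numeric()
    if (lamMax > 0) {
      cand <- .poissonTimes(lamMax, 0, span)
      if (length(cand)) {
        lam <- .unitLambda(cand, a[i], bvec, tr$onset_s, tr$trial_end_s,
                           config@interval)
        st <- cand[runif(length(cand)) < lam / lamMax]
      }
    }
    st <- sort(unique(st))
    units[[i]] <- new("SpikeUnit",
                      unitId = sprintf("U%03d", i),
                      sessionId = sid,
                      animalId = tr$animal_id[1L],
                      spikeTimes = st,
                      waveform = wfs$waveforms[[i]],
                      samplingRate = wfs$samplingRate,
                      meanRate = length(st) / span,
                      truth = list(a = a[i],
                                   b = config@rampSlope,
                                   isRamping = isRamping[i],
                                   klass = wfs$klass[i],
                                   p2t_ms = wfs$p2t_ms[i],
                                   hpw_ms = wfs$hpw_ms[i]))
  }
  units
}

#' Simulate a complete experiment
#'
#' Runs \code{\link{simulateBehavior}} and \code{\link{simulateSpikes}}
#' under one root seed and returns the bundled \linkS4class{FiSession}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{FiSession}.
#' @examples
#' ses <- simulateExperiment(simConfig(seed = 3, nAnimals = 2, nOpsin = 1,
#'                                     sessionMinutes = 5, nUnits = 4))
#' ses
#' @export
simulateExperiment <- function(config) {
  tr <- simulateBehavior(config)
  units <- simulateSpikes(config, tr)
  new("FiSession", trials = tr, units = units, config = config)
}
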