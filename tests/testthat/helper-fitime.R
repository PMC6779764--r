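## Shared fixtures and independent oracles for the test suite.

## Build a minimal trial table from a list of response-time vectors.
makeTrials <- function(responseList, animal = "A01", drug = "saline",
                       stim = "NoStim", session = NULL, onsetStep = 30) {
  n <- length(responseList)
  df <- data.frame(
    animal_id = rep_len(animal, n),
    virus = rep_len("ChR2", n),
    session_id = if (is.null(session))
      paste0(rep_len(animal, n), "_", rep_len(drug, n), "_1")[seq_len(n)]
      else rep_len(session, n),
    trial_index = seq_len(n),
    drug = rep_len(drug, n),
    stim = rep_len(stim, n),
    onset_s = (seq_len(n) - 1) * onsetStep,
    iti_s = rep_len(8, n),
    reward_time_s = rep_len(NA_real_, n),
    trial_end_s = rep_len(24, n),
    true_start_s = rep_len(NA_real_, n),
    stringsAsFactors = FALSE)
  df$response_times <- responseList
  df
}

## Independent brute-force oracle for the start-time objective: evaluates
## D(s) = s (r - r1) + (T - s)(r2 - r) at every candidate with plain loops.
bruteStart <- function(times, T) {
  times <- sort(times)
  N <- length(times)
  r <- N / T
  cand <- unique(c(0, times, T))
  D <- numeric(length(cand))
  for (k in seq_along(cand)) {
    s <- cand[k]
    n1 <- 0
    for (t in times) if (t < s) n1 <- n1 + 1
    r1 <- if (s > 0) n1 / s else 0
    r2 <- if (s < T) (N - n1) / (T - s) else 0
    D[k] <- s * (r - r1) + (T - s) * (r2 - r)
  }
  best <- which(D >= max(D) - 1e-9)[1L]   # earliest among numeric ties
  list(start = cand[best], objective = D[best])
}

## Closed-form least-squares slope, independent of lm().
olsSlope <- function(x, y) sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)

## Independent inhomogeneous-Poisson sampler (thinning) used to construct
## spike trains with known rate profiles for ephys tests.
rInhom <- function(a, b, T) {
  lamMax <- max(a, a + b * T, 0)
  if (lamMax <= 0) return(numeric())
  n <- rpois(1, lamMax * T)
  cand <- sort(runif(n, 0, T))
  cand[runif(length(cand)) < pmax(0, a + b * cand) / lamMax]
}

## Assemble a SpikeUnit from per-trial spike times on the trial clock.
makeUnit <- function(perTrial, trialsDf, id = "U001", waveform = NULL,
                     samplingRate = 40000) {
  st <- sort(unlist(mapply(function(sp, on) sp + on, perTrial,
                           trialsDf$onset_s, SIMPLIFY = FALSE)))
  span <- max(trialsDf$onset_s + trialsDf$trial_end_s)
  if (is.null(waveform)) {
    tt <- seq(0, 2.5, by = 1 / 40)
    waveform <- -100 * exp(-(tt - 0.8)^2 / (2 * 0.1^2)) +
      40 * exp(-(tt - 1.4)^2 / (2 * 0.16^2))
  }
  methods::new("SpikeUnit", unitId = id,
               sessionId = trialsDf$session_id[1L],
               animalId = trialsDf$animal_id[1L],
               spikeTimes = st, waveform = waveform,
               samplingRate = samplingRate,
               meanRate = length(st) / span, truth = list())
}

quietly <- function(expr) suppressWarnings(suppressMessages(expr))
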