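#' @include AllClasses.R
NULL

#' Curvature index of a cumulative response record
#'
#' Quantifies temporal control of responding within a fixed interval as the
#' deviation of the cumulative response record from the straight line that
#' a constant response rate would trace.  Values lie in [-1, 1]: 0 for a
#' constant rate, positive when responding is concentrated late in the
#' interval (the scalloped records characteristic of timed behaviour),
#' negative when concentrated early.  The index is invariant to overall
#' response rate, to time rescaling, and is robust to smoothing or
#' binning choices.
#'
#' Two variants are provided.  \code{"fry_discrete"} divides the interval
#' into \code{nSegments} equal segments and evaluates
#' \deqn{C = \frac{(n-1) R_n - 2 \sum_{i=1}^{n-1} R_i}{n R_n},}
#' where \eqn{R_i} is the cumulative response count at the end of segment
#' \eqn{i}; its range is \eqn{\pm (n-1)/n}.  \code{"trapezoid_continuous"}
#' computes \eqn{(A_{line} - A_{record}) / A_{line}} with
#' \eqn{A_{line} = T R_n / 2} and \eqn{A_{record}} the trapezoidal area
#' under the cumulative record traced through its vertices
#' \eqn{(0,0), (t_{(i)}, i), (T, R_n)}; the two variants agree in the
#' large-\eqn{n} limit.
#'
#' @param times response times, seconds in \code{[0, interval]}.
#' @param interval the fixed interval T, seconds.
#' @param nSegments number of equal segments for the discrete variant
#'   (>= 2); 1000 by default, where the discrete value is within 1/1000 of
#'   the continuous one.
#' @param method "fry_discrete" or "trapezoid_continuous".
#' @return a \linkS4class{CurvatureResult}; \code{curvatureValue()} is NA
#'   and \code{@defined} FALSE when \code{times} is empty.
#' @examples
#' ## constant response rate: one press at the end of each of 4 segments
#' curvatureValue(curvatureIndex(c(3, 6, 9, 12), 12, nSegments = 4))  # 0
#' ## all presses late
#' curvatureValue(curvatureIndex(rep(11.9, 10), 12, nSegments = 4))   # 3/4
#' @export
curvatureIndex <- function(times, interval,
                           nSegments = 1000L,
                           method = c("fry_discrete", "trapezoid_continuous")) {
  method <- match.arg(method)
  stopifnot(interval > 0)
  if (nSegments < 2) stop("nSegments must be at least 2")
  times <- as.numeric(times)
  if (any(times < 0 | times > interval))
    stop("response times must lie within [0, interval]")
  N <- length(times)
  if (N == 0L)
    return(new("CurvatureResult", value = NA_real_,
               nSegments = as.integer(nSegments), method = method,
               totalResponses = 0L, defined = FALSE))
  times <- sort(times)
  if (method == "fry_discrete") {
    n <- as.integer(nSegments)
    bounds <- interval * seq_len(n) / n
    R <- vapply(bounds, function(b) sum(times <= b), numeric(1))
    value <- ((n - 1) * R[n] - 2 * sum(R[seq_len(n - 1L)])) / (n * R[n])
  } else {
    aLine <- interval * N / 2
    heights <- seq_len(N)
    aRec <- sum(diff(c(0, times)) * (heights - 0.5)) +
      (interval - times[N]) * N
    value <- (aLine - aRec) / aLine
  }
  new("CurvatureResult", value = value, nSegments = as.integer(nSegments),
      method = method, totalResponses = N, defined = TRUE)
}

## change-point objective: rate contrast about a candidate break s
.startObjective <- function(times, T, s) {
  N <- length(times)
  r <- N / T
  r1 <- if (s > 0) sum(times < s) / s else 0
  r2 <- if (s < T) sum(times >= s) / (T - s) else 0
  s * (r - r1) + (T - s) * (r2 - r)
}

#' Detect the single-trial start time of responding
#'
#' Estimates, for one trial, the moment of transition from a low to a high
#' response rate by exhaustive search over candidate breakpoints (every
#' response time plus the interval endpoints).  The objective contrasts
#' the rates before and after a candidate \eqn{s} against the overall rate
#' \eqn{r = N/T}:
#' \deqn{D(s) = s (r - r_1) + (T - s)(r_2 - r),}
#' with \eqn{r_1} the rate on \eqn{[0, s)} and \eqn{r_2} the rate on
#' \eqn{[s, T)}; the earliest maximising candidate wins ties.  This is the
#' two-rate (start-only) special case of the three-state single-trial
#' analysis developed for peak-interval timing; a fixed-interval trial has
#' no stop, so only the low-to-high change point is sought.
#'
#' @param responses sorted response times, seconds in \code{[0, T]}.
#' @param interval the fixed interval T, seconds.
#' @param rMin minimum number of responses for a valid estimate (default 2);
#'   below it \code{valid} is FALSE and the trial should be excluded from
#'   start-time summaries.
#' @return a \linkS4class{StartTimeResult}.
#' @examples
#' detectStartTime(c(8, 8.5, 9, 9.5, 10), 12)   # start at 8 s
#' @export
detectStartTime <- function(responses, interval, rMin = 2L) {
  stopifnot(interval > 0)
  responses <- sort(as.numeric(responses))
  if (length(responses) && (responses[1L] < 0 ||
                            responses[length(responses)] > interval))
    stop("responses must lie within [0, interval]")
  N <- length(responses)
  if (N < rMin)
    return(new("StartTimeResult", start = NA_real_, objective = NA_real_,
               nResponses = as.integer(N), valid = FALSE))
  cand <- unique(c(0, responses, interval))
  D <- vapply(cand, function(s) .startObjective(responses, interval, s),
              numeric(1))
  ## earliest maximiser; candidates within 1e-9 of the maximum are treated
  ## as exact ties (repeated response times make mathematically equal
  ## objectives differ by floating-point noise)
  best <- which(D >= max(D) - 1e-9)[1L]
  new("StartTimeResult", start = cand[best], objective = D[best],
      nResponses = as.integer(N), valid = TRUE)
}

#' Kernel-density time-response histogram
#'
#' Pools response times across each animal's trials and evaluates a
#' Gaussian-kernel response-rate curve on a regular grid over the interval,
#' scaled so each animal's curve peaks at 1 before cross-animal averaging
#' (so animals with different overall press rates contribute equal shapes).
#' Raw binned rates in presses/s are returned alongside.
#'
#' @param trials trial table (see \code{\link{simulateBehavior}}); only
#'   responses within \code{[0, interval]} are used.
#' @param bandwidth Gaussian kernel SD, seconds (default 1).
#' @param bin grid step, seconds (default 0.1).
#' @param interval the fixed interval, seconds.
#' @return list with \code{perAnimal} (data.frame: animal_id, time,
#'   rate_raw, rate_kde, rate_norm), \code{average} (data.frame: time,
#'   rate_norm mean and SEM across animals), and \code{emptyAnimals}
#'   (animals with zero responses, flagged rather than divided by zero).
#' @export
timeResponseHistogram <- function(trials, bandwidth = 1, bin = 0.1,
                                  interval = 12) {
  stopifnot(nrow(trials) > 0)
  grid <- seq(0, interval, by = bin)
  animals <- unique(trials$animal_id)
  per <- list()
  empty <- character()
  for (a in animals) {
    tr <- trials[trials$animal_id == a, ]
    resp <- unlist(tr$response_times)
    resp <- resp[resp >= 0 & resp <= interval]
    nTrials <- nrow(tr)
    if (!length(resp)) {
      empty <- c(empty, a)
      next
    }
    kde <- vapply(grid, function(g) sum(dnorm(g, resp, bandwidth)), numeric(1))
    kde <- kde / nTrials                       # presses/s, smoothed
    edges <- c(grid - bin / 2, interval + bin / 2)
    raw <- vapply(seq_along(grid), function(i)
      sum(resp >= edges[i] & resp < edges[i + 1L]), numeric(1)) / (nTrials * bin)
    per[[a]] <- data.frame(animal_id = a, time = grid, rate_raw = raw,
                           rate_kde = kde, rate_norm = kde / max(kde),
                           stringsAsFactors = FALSE)
  }
  perAnimal <- .rbindRows(per)
  average <- NULL
  if (!is.null(perAnimal)) {
    m <- tapply(perAnimal$rate_norm, perAnimal$time, mean)
    s <- tapply(perAnimal$rate_norm, perAnimal$time,
                function(x) sd(x) / sqrt(length(x)))
    average <- data.frame(time = as.numeric(names(m)),
                          rate_norm = as.numeric(m), sem = as.numeric(s))
    average <- average[order(average$time), ]
    rownames(average) <- NULL
  }
  list(perAnimal = perAnimal, average = average, emptyAnimals = empty)
}

#' Per-condition behavioural summary
#'
#' For every (animal, drug, stim) cell: the curvature index of the pooled
#' within-interval responses, the mean detected start time over valid
#' trials, and bookkeeping counts (trials, responses, trials excluded from
#' start detection for having too few responses).
#'
#' @param trials trial table.
#' @param interval fixed interval, seconds.
#' @param nSegments,method passed to \code{\link{curvatureIndex}}.
#' @param rMin passed to \code{\link{detectStartTime}}.
#' @return tidy data.frame with one row per condition cell; cells with no
#'   responses carry NA curvature and are reported, not dropped.
#' @export
sessionBehaviorSummary <- function(trials, interval = 12, nSegments = 1000L,
                                   method = "fry_discrete", rMin = 2L) {
  stopifnot(nrow(trials) > 0)
  cells <- unique(trials[, c("animal_id", "drug", "stim")])
  cells <- cells[order(cells$animal_id, cells$drug, cells$stim), ]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- trials$animal_id == cells$animal_id[i] &
      trials$drug == cells$drug[i] & trials$stim == cells$stim[i]
    tr <- trials[sel, ]
    respList <- lapply(tr$response_times, function(x)
      x[x >= 0 & x <= interval])
    pooled <- unlist(respList)
    curv <- curvatureIndex(pooled, interval, nSegments, method)
    starts <- vapply(respList, function(x) {
      st <- detectStartTime(x, interval, rMin)
      if (st@valid) st@start else NA_real_
    }, numeric(1))
    out[[i]] <- data.frame(
      animal_id = cells$animal_id[i],
      drug = cells$drug[i],
      stim = cells$stim[i],
      curvature = curvatureValue(curv),
      mean_start_s = if (any(!is.na(starts))) mean(starts, na.rm = TRUE)
                     else NA_real_,
      n_trials = nrow(tr),
      n_responses = length(pooled),
      n_start_excluded = sum(is.na(starts)),
      stringsAsFactors = FALSE)
  }
  res <- .rbindRows(out)
  if (any(is.na(res$curvature)))
    message("behaviour summary: ", sum(is.na(res$curvature)),
            " condition cell(s) had no responses")
  res
}

#' Per-trial start times for a trial table
#'
#' Runs \code{\link{detectStartTime}} on every trial and returns a tidy
#' table, including invalid trials (too few responses) with NA starts.
#'
#' @inheritParams sessionBehaviorSummary
#' @return data.frame with animal_id, session_id, trial_index, drug, stim,
#'   n_responses, start_s, valid.
#' @export
trialStartTimes <- function(trials, interval = 12, rMin = 2L) {
  res <- lapply(seq_len(nrow(trials)), function(i) {
    resp <- trials$response_times[[i]]
    resp <- resp[resp >= 0 & resp <= interval]
    st <- detectStartTime(resp, interval, rMin)
    data.frame(animal_id = trials$animal_id[i],
               session_id = trials$session_id[i],
               trial_index = trials$trial_index[i],
               drug = trials$drug[i], stim = trials$stim[i],
               n_responses = st@nResponses,
               start_s = if (st@valid) st@start else NA_real_,
               valid = st@valid, stringsAsFactors = FALSE)
  })
  .rbindRows(res)
}
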