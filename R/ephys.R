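#' @include AllClasses.R
NULL

## linear-interpolated crossing time of `level` between samples i and i+1
.crossTime <- function(tt, w, i, level) {
  tt[i] + (level - w[i]) * (tt[i + 1L] - tt[i]) / (w[i + 1L] - w[i])
}

#' Extract waveform features
#'
#' Measures the two scalar features used for unit classification from a
#' mean spike waveform: the peak-to-trough duration (time from the
#' principal extremum to the subsequent extremum of opposite sign) and the
#' half-peak width (width of the principal extremum at half its amplitude,
#' found by linear interpolation between samples).  Polarity is detected
#' from the extremum of largest magnitude, so a waveform and its negation
#' yield identical features.
#'
#' @param waveform numeric samples (microvolts; any consistent unit).
#' @param samplingRate sampling rate, Hz.
#' @return list with \code{p2t_ms}, \code{hpw_ms}, \code{polarity}
#'   (-1 when the principal extremum is a trough).
#' @examples
#' cfg <- simConfig(seed = 4)
#' wf <- simulateWaveforms(cfg, 1, klass = "MSN")
#' extractFeatures(wf$waveforms[[1]], wf$samplingRate)
#' @export
extractFeatures <- function(waveform, samplingRate) {
  w <- as.numeric(waveform)
  if (length(w) < 3L || diff(range(w)) == 0)
    stop("flat or degenerate waveform: cannot extract features")
  tt <- (seq_along(w) - 1L) / samplingRate * 1000   # ms
  iMain <- which.max(abs(w))
  pol <- sign(w[iMain])
  wp <- w * pol           # principal extremum now a positive peak
  iMain <- which.max(wp)
  after <- wp[seq.int(iMain, length(wp))]
  iOpp <- iMain - 1L + which.min(after)
  if (iOpp == iMain || -wp[iOpp] <= 0)
    stop("no subsequent opposite extremum found")
  half <- wp[iMain] / 2
  iL <- max(which(wp[seq_len(iMain)] < half))
  iR <- iMain - 1L + min(which(wp[seq.int(iMain, length(wp))] < half))
  if (!is.finite(iL) || !is.finite(iR))
    stop("half-amplitude level not crossed on both sides")
  tL <- .crossTime(tt, wp, iL, half)
  tR <- .crossTime(tt, wp, iR - 1L, half)
  list(p2t_ms = tt[iOpp] - tt[iMain], hpw_ms = tR - tL, polarity = pol)
}

#' Classify units into MSN and FSI by waveform features
#'
#' Fits a full-covariance Gaussian mixture to the (peak-to-trough
#' duration, half-peak width) feature pairs and assigns each unit the
#' maximum-posterior component; the component with the larger mean
#' peak-to-trough duration is labelled MSN (medium spiny neurons have
#' broad waveforms, fast-spiking interneurons narrow ones).  BIC chooses
#' between one and two components, so a sample drawn from a single class
#' is tolerated and labelled as one class (broad/narrow boundary at a
#' 0.4-ms peak-to-trough duration).
#' The fit uses deterministic model-based hierarchical initialisation, so
#' results do not depend on input order or RNG state.
#'
#' @param features data.frame with columns \code{p2t_ms} and \code{hpw_ms}
#'   (one row per unit), e.g. from \code{\link{extractFeatures}}.
#' @param seed kept for API stability; the fit itself is deterministic.
#' @return the input with columns \code{klass} ("MSN"/"FSI") and
#'   \code{posterior} (probability of the assigned class, in [0.5, 1]).
#' @importFrom mclust Mclust mclustBIC
#' @export
classifyUnits <- function(features, seed = 1L) {
  stopifnot(is.data.frame(features),
            all(c("p2t_ms", "hpw_ms") %in% names(features)))
  if (nrow(features) < 2L) stop("need at least 2 units to classify")
  X <- as.matrix(features[, c("p2t_ms", "hpw_ms")])
  ## order-invariant initialisation: hierarchical agglomeration on sorted data
  ord <- order(X[, 1L], X[, 2L])
  fit <- tryCatch(
    mclust::Mclust(X[ord, , drop = FALSE], G = 1:2, modelNames = "VVV",
                   verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$parameters)) {
    message("full-covariance mixture degenerate; falling back to diagonal")
    fit <- mclust::Mclust(X[ord, , drop = FALSE], G = 1:2, modelNames = "VVI",
                          verbose = FALSE)
  }
  if (is.null(fit) || fit$G == 1L) {
    ## one component: a single waveform class; label it by the broad/narrow
    ## boundary conventional for striatal units (~0.4 ms peak-to-trough)
    lab <- if (mean(X[, "p2t_ms"]) >= 0.4) "MSN" else "FSI"
    features$klass <- rep(lab, nrow(features))
    features$posterior <- rep(1, nrow(features))
    return(features)
  }
  msnComp <- which.max(fit$parameters$mean["p2t_ms", ])
  lab <- ifelse(fit$classification == msnComp, "MSN", "FSI")
  post <- fit$z[cbind(seq_len(nrow(X)), fit$classification)]
  inv <- order(ord)
  features$klass <- lab[inv]
  features$posterior <- post[inv]
  features
}

#' Filter units on firing rate and class
#'
#' Keeps units whose session mean rate is strictly above \code{minRate}
#' (the standard 0.1-Hz inclusion threshold: a unit at exactly 0.1 Hz is
#' dropped) and whose assigned class matches \code{klass}.  Removal counts
#' per criterion are reported via a message and attached as an attribute.
#'
#' @param units list of \linkS4class{SpikeUnit}.
#' @param klasses character vector of assigned classes, parallel to
#'   \code{units}; NULL skips the class filter.
#' @param minRate inclusion threshold, Hz.
#' @param klass class to keep (default "MSN").
#' @return filtered list with attribute \code{removed}
#'   (\code{c(rate = ..., class = ...)}).
#' @export
filterUnits <- function(units, klasses = NULL, minRate = 0.1, klass = "MSN") {
  rates <- vapply(units, function(u) u@meanRate, numeric(1))
  keepRate <- rates > minRate
  keepClass <- if (is.null(klasses)) rep(TRUE, length(units))
               else klasses == klass
  removed <- c(rate = sum(!keepRate), class = sum(keepRate & !keepClass))
  keep <- keepRate & keepClass
  message(sprintf("filterUnits: kept %d/%d (removed %d below %.2g Hz, %d not %s)",
                  sum(keep), length(units), removed[["rate"]], minRate,
                  removed[["class"]], klass))
  out <- units[keep]
  attr(out, "removed") <- removed
  out
}

#' Bin spikes within trials
#'
#' Counts spikes in half-open bins \code{[t, t + bin)} of the trial clock
#' across the fixed interval; a spike exactly at the interval end is
#' outside \code{[0, interval)} and excluded.
#'
#' @param unit a \linkS4class{SpikeUnit} (session-clock spike times).
#' @param trials trial table rows whose \code{onset_s} align spikes to the
#'   trial clock.
#' @param bin bin width, seconds (default 0.01 = 10 ms).
#' @param interval fixed interval, seconds.
#' @return integer matrix, trials x bins, with bin-centre times (s) in
#'   \code{dimnames[[2]]}.
#' @export
binFiring <- function(unit, trials, bin = 0.01, interval = 12) {
  stopifnot(is(unit, "SpikeUnit"), nrow(trials) > 0)
  nb <- as.integer(round(interval / bin))
  st <- unit@spikeTimes
  if (length(st) && nrow(trials) &&
      (max(st) < min(trials$onset_s) - interval ||
       min(st) > max(trials$onset_s) + 10 * interval))
    stop("spike times do not overlap the trial span: misaligned clocks?")
  m <- matrix(0L, nrow(trials), nb)
  edges <- seq(0, interval, by = bin)
  for (i in seq_len(nrow(trials))) {
    rel <- st - trials$onset_s[i]
    rel <- rel[rel >= 0 & rel < interval]
    if (length(rel))
      m[i, ] <- tabulate(findInterval(rel, edges), nbins = nb)
  }
  centers <- edges[-length(edges)] + bin / 2
  dimnames(m) <- list(NULL, formatC(centers, format = "fg"))
  m
}

#' Per-neuron time-ramping regression
#'
#' Regresses a unit's unsmoothed, unnormalized binned firing rate on time
#' within the interval, pooling all supplied trials (typically one
#' (drug, stim) condition cell).  A unit whose time coefficient has
#' p < 0.05 is flagged as exhibiting time-dependent ramping; no
#' multiple-testing correction is applied, matching field practice for
#' this per-neuron screen.
#'
#' @param unit a \linkS4class{SpikeUnit}.
#' @param trials trial rows defining the condition cell (>= 2 trials).
#' @param bin bin width, seconds (default 10 ms).
#' @param interval fixed interval, seconds.
#' @param family "gaussian" for ordinary least squares on rates
#'   (spikes/s), or "poisson" for a log-link count regression with the bin
#'   width as exposure.
#' @return one-row data.frame: unit_id, slope (spikes/s per s), intercept
#'   (spikes/s), p_time, is_ramping, n_trials, n_obs.  All-zero firing
#'   returns slope 0 and p 1 by convention.
#' @export
fitRamping <- function(unit, trials, bin = 0.01, interval = 12,
                       family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  if (nrow(trials) < 2L) stop("need at least 2 trials in the condition cell")
  counts <- binFiring(unit, trials, bin, interval)
  tvec <- rep(as.numeric(colnames(counts)), each = nrow(counts))
  y <- as.vector(counts)
  if (all(y == 0)) {
    message("fitRamping: unit ", unit@unitId, " silent in cell; slope 0, p 1")
    return(data.frame(unit_id = unit@unitId, slope = 0, intercept = 0,
                      p_time = 1, is_ramping = FALSE,
                      n_trials = nrow(trials), n_obs = length(y),
                      stringsAsFactors = FALSE))
  }
  if (family == "gaussian") {
    rate <- y / bin
    fit <- lm(rate ~ tvec)
    sm <- summary(fit)$coefficients
    slope <- sm["tvec", "Estimate"]
    intercept <- sm["(Intercept)", "Estimate"]
    p <- sm["tvec", "Pr(>|t|)"]
    if (is.na(p)) {         # zero residual variance: noiseless input
      slope <- unname(slope)
      p <- if (abs(slope) > 1e-12) 0 else 1
    }
  } else {
    fit <- stats::glm(y ~ tvec, family = stats::poisson(),
                      offset = rep(log(bin), length(y)))
    sm <- summary(fit)$coefficients
    slope <- sm["tvec", "Estimate"]          # log-rate slope, 1/s
    intercept <- exp(sm["(Intercept)", "Estimate"])
    p <- sm["tvec", "Pr(>|z|)"]
  }
  data.frame(unit_id = unit@unitId, slope = slope, intercept = intercept,
             p_time = p, is_ramping = p < 0.05,
             n_trials = nrow(trials), n_obs = length(y),
             stringsAsFactors = FALSE)
}

#' Ramping fits for all units by condition cell
#'
#' Applies \code{\link{fitRamping}} to every unit in every (drug, stim)
#' cell of its own session's trials.
#'
#' @param units list of \linkS4class{SpikeUnit}.
#' @param trials full trial table.
#' @param ... passed to \code{\link{fitRamping}}.
#' @return data.frame of fits with drug and stim columns.
#' @export
rampingFits <- function(units, trials, ...) {
  out <- list()
  for (u in units) {
    tr <- trials[trials$session_id == u@sessionId, ]
    cells <- unique(tr[, c("drug", "stim")])
    for (i in seq_len(nrow(cells))) {
      cell <- tr[tr$drug == cells$drug[i] & tr$stim == cells$stim[i], ]
      if (nrow(cell) < 2L) next
      f <- fitRamping(u, cell, ...)
      f$drug <- cells$drug[i]
      f$stim <- cells$stim[i]
      out[[length(out) + 1L]] <- f
    }
  }
  .rbindRows(out)
}

## Gaussian smoothing of a series sampled at `bin` with kernel SD `bw` (s)
.gaussSmooth <- function(x, bin, bw) {
  if (bw <= 0) return(x)
  half <- ceiling(4 * bw / bin)
  k <- dnorm(seq(-half, half) * bin, 0, bw)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1L], half), x, rep(x[n], half))   # edge replication
  as.numeric(stats::filter(xp, k, sides = 2))[half + seq_len(n)]
}

#' Build a PC1-sorted PETH matrix
#'
#' For each unit: trial-averaged firing rate in \code{bin}-wide bins over
#' the interval, z-scored across bins, then Gaussian-smoothed (for display
#' matrices only; regressions elsewhere always use unsmoothed rates).  The
#' unit-by-bin matrix is sorted by loading on its first principal
#' component, whose sign is fixed so positive loadings correspond to
#' increasing-in-time profiles; upward-ramping units therefore gather at
#' one edge of the heat map.
#'
#' @param units list of \linkS4class{SpikeUnit} (>= 2).
#' @param trials trial rows to average over (e.g. one stimulation
#'   condition); each unit uses the rows of its own session.
#' @param bin bin width, seconds (default 0.1 = 100 ms).
#' @param bandwidth smoothing kernel SD, seconds (default 0.5).
#' @param interval fixed interval, seconds.
#' @return a \linkS4class{PethMatrix}; zero-variance units are kept as
#'   all-zero placeholder rows and flagged in \code{rowData()$zero_variance}.
#' @export
buildPeth <- function(units, trials, bin = 0.1, bandwidth = 0.5,
                      interval = 12) {
  stopifnot(length(units) >= 2L)
  nb <- as.integer(round(interval / bin))
  rate <- z <- matrix(NA_real_, length(units), nb)
  zeroVar <- logical(length(units))
  for (i in seq_along(units)) {
    u <- units[[i]]
    tr <- trials[trials$session_id == u@sessionId, ]
    if (!nrow(tr)) tr <- trials
    counts <- binFiring(u, tr, bin, interval)
    r <- colMeans(counts) / bin
    rate[i, ] <- r
    if (sd(r) == 0) {
      zeroVar[i] <- TRUE
      z[i, ] <- 0
    } else {
      z[i, ] <- .gaussSmooth((r - mean(r)) / sd(r), bin, bandwidth)
    }
  }
  if (any(zeroVar))
    message("buildPeth: ", sum(zeroVar),
            " zero-variance unit(s) kept as placeholder rows")
  centers <- seq(bin / 2, interval - bin / 2, by = bin)
  pca <- prcomp(z, center = TRUE, scale. = FALSE)
  pc1 <- pca$rotation[, 1L]
  if (stats::cor(pc1, centers) < 0) pc1 <- -pc1   # positive = ramping up
  loading <- as.numeric(scale(z, center = TRUE, scale = FALSE) %*% pc1)
  ord <- order(loading)
  ids <- vapply(units, function(u) u@unitId, character(1))
  se <- SummarizedExperiment(
    assays = list(z = z, rate = rate),
    rowData = DataFrame(unit_id = ids, pc1_loading = loading,
                        zero_variance = zeroVar),
    colData = DataFrame(time_s = centers))
  rownames(se) <- ids
  new("PethMatrix", se, bin = bin, bandwidth = bandwidth,
      sortOrder = as.integer(ord))
}
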