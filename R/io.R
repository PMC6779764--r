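#' @include simulate.R
NULL

.BUNDLE_FILES <- c("trials.csv", "spikes.csv", "units.csv", "config.yaml")

.configToList <- function(cfg) {
  mat2list <- function(m) {
    l <- lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
    names(l) <- rownames(m)
    l
  }
  list(seed = cfg@seed, nAnimals = cfg@nAnimals, nOpsin = cfg@nOpsin,
       nSessionsPerCondition = cfg@nSessionsPerCondition,
       sessionMinutes = cfg@sessionMinutes, interval = cfg@interval,
       itiChoices = as.list(cfg@itiChoices),
       stimLevels = as.list(cfg@stimLevels),
       drugLevels = as.list(cfg@drugLevels),
       startMu = mat2list(cfg@startMu), startCv = cfg@startCv,
       animalSd = cfg@animalSd, startDist = cfg@startDist,
       rateLow = cfg@rateLow, rateHigh = cfg@rateHigh, timeout = cfg@timeout,
       nUnits = cfg@nUnits, fracRamping = cfg@fracRamping,
       rampIntercept = cfg@rampIntercept,
       rampInterceptSd = cfg@rampInterceptSd,
       rampSlope = mat2list(cfg@rampSlope), fracFsi = cfg@fracFsi,
       waveformParams = lapply(cfg@waveformParams, lapply, as.list),
       waveformHz = cfg@waveformHz)
}

.configFromList <- function(l) {
  drugs <- unlist(l$drugLevels)
  stims <- unlist(l$stimLevels)
  list2mat <- function(x) {
    m <- do.call(rbind, lapply(x, function(r) unlist(r)[stims]))
    rownames(m) <- names(x)
    m[drugs, stims, drop = FALSE]
  }
  simConfig(seed = l$seed, nAnimals = l$nAnimals, nOpsin = l$nOpsin,
            nSessionsPerCondition = l$nSessionsPerCondition,
            sessionMinutes = l$sessionMinutes, interval = l$interval,
            itiChoices = unlist(l$itiChoices), stimLevels = stims,
            drugLevels = drugs, startMu = list2mat(l$startMu),
            startCv = l$startCv, animalSd = l$animalSd,
            startDist = l$startDist, rateLow = l$rateLow,
            rateHigh = l$rateHigh, timeout = l$timeout, nUnits = l$nUnits,
            fracRamping = l$fracRamping, rampIntercept = l$rampIntercept,
            rampInterceptSd = l$rampInterceptSd,
            rampSlope = list2mat(l$rampSlope), fracFsi = l$fracFsi,
            waveformParams = lapply(l$waveformParams, lapply, unlist),
            waveformHz = l$waveformHz)
}

#' Write a session bundle
#'
#' Persists a \linkS4class{FiSession} as the plain-text bundle the
#' pipeline reads back: \code{trials.csv} (one row per trial;
#' \code{response_times} semicolon-joined seconds), \code{spikes.csv}
#' (long: unit_id, session_id, spike_time_s), \code{units.csv} (unit
#' metadata, generative truth when present, and waveform sample columns
#' \code{wf_*}), a \code{config.yaml} echo of the generating
#' configuration, and \code{manifest.json} with md5 checksums, the seed
#' and the package version.
#'
#' @param session a \linkS4class{FiSession}.
#' @param path directory to create/write into.
#' @return invisibly, the manifest list.
#' @export
writeBundle <- function(session, path) {
  stopifnot(is(session, "FiSession"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tr <- session@trials
  out <- tr[, c("animal_id", "session_id", "trial_index", "drug", "stim",
                "onset_s", "iti_s", "reward_time_s")]
  out$response_times <- vapply(tr$response_times, function(x)
    paste(format(x, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = ";"), character(1))
  for (extra in c("virus", "trial_end_s", "true_start_s"))
    if (extra %in% names(tr)) out[[extra]] <- tr[[extra]]
  write.csv(out, file.path(path, "trials.csv"), row.names = FALSE)

  units <- session@units
  spikes <- do.call(rbind, lapply(units, function(u)
    if (length(u@spikeTimes))
      data.frame(unit_id = u@unitId, session_id = u@sessionId,
                 spike_time_s = u@spikeTimes, stringsAsFactors = FALSE)))
  if (is.null(spikes))
    spikes <- data.frame(unit_id = character(), session_id = character(),
                         spike_time_s = numeric())
  write.csv(spikes, file.path(path, "spikes.csv"), row.names = FALSE)

  wfLen <- max(c(0L, vapply(units, function(u) length(u@waveform), integer(1))))
  urows <- lapply(units, function(u) {
    wf <- c(u@waveform, rep(NA_real_, wfLen - length(u@waveform)))
    tr <- u@truth
    d <- data.frame(unit_id = u@unitId, session_id = u@sessionId,
                    animal_id = u@animalId,
                    sampling_rate_hz = u@samplingRate,
                    mean_rate_hz = u@meanRate,
                    true_class = if (!is.null(tr$klass)) tr$klass else NA,
                    true_a = if (!is.null(tr$a)) tr$a else NA,
                    true_is_ramping = if (!is.null(tr$isRamping))
                      tr$isRamping else NA,
                    stringsAsFactors = FALSE)
    if (wfLen) d[sprintf("wf_%03d", seq_len(wfLen))] <- as.list(wf)
    d
  })
  ucsv <- .rbindRows(urows)
  if (is.null(ucsv))
    ucsv <- data.frame(unit_id = character(), session_id = character(),
                       animal_id = character(), sampling_rate_hz = numeric(),
                       mean_rate_hz = numeric())
  write.csv(ucsv, file.path(path, "units.csv"), row.names = FALSE)

  cfg <- session@config
  yaml::write_yaml(if (is.null(cfg)) list() else .configToList(cfg),
                   file.path(path, "config.yaml"))
  manifest <- list(
    seed = if (is.null(cfg)) NA else cfg@seed,
    package_version = as.character(packageVersion("fitime")),
    checksums = as.list(tools::md5sum(file.path(path, .BUNDLE_FILES))))
  names(manifest$checksums) <- .BUNDLE_FILES
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read and validate a session bundle
#'
#' Loads a bundle written by \code{\link{writeBundle}} into typed objects,
#' validating as it goes: required files present, manifest checksums
#' match, and every spike's \code{unit_id} resolves in \code{units.csv}.
#' All violations are collected and reported together in one error, not
#' just the first.
#'
#' @param path bundle directory.
#' @param checkChecksums verify manifest md5 sums (default TRUE).
#' @return a \linkS4class{FiSession}.
#' @export
readBundle <- function(path, checkChecksums = TRUE) {
  problems <- character()
  missing <- .BUNDLE_FILES[!file.exists(file.path(path, .BUNDLE_FILES))]
  if (length(missing))
    stop("bundle at ", path, " is missing: ", paste(missing, collapse = ", "))
  manifestPath <- file.path(path, "manifest.json")
  if (checkChecksums && file.exists(manifestPath)) {
    manifest <- jsonlite::read_json(manifestPath)
    for (f in names(manifest$checksums)) {
      actual <- unname(tools::md5sum(file.path(path, f)))
      if (!identical(actual, manifest$checksums[[f]]))
        problems <- c(problems, sprintf("checksum mismatch for %s", f))
    }
  }
  tr <- read.csv(file.path(path, "trials.csv"), stringsAsFactors = FALSE)
  missCols <- setdiff(.TRIAL_COLUMNS, names(tr))
  if (length(missCols))
    problems <- c(problems, paste("trials.csv missing columns:",
                                  paste(missCols, collapse = ", ")))
  if (!length(missCols)) {
    tr$response_times <- lapply(tr$response_times, function(s) {
      if (is.na(s) || !nzchar(s)) numeric()
      else as.numeric(strsplit(s, ";", fixed = TRUE)[[1L]])
    })
  }
  spikes <- read.csv(file.path(path, "spikes.csv"), stringsAsFactors = FALSE)
  ucsv <- read.csv(file.path(path, "units.csv"), stringsAsFactors = FALSE,
                   check.names = FALSE)
  dangling <- setdiff(unique(spikes$unit_id), ucsv$unit_id)
  if (length(dangling))
    problems <- c(problems,
                  paste("spikes.csv references unknown unit(s):",
                        paste(dangling, collapse = ", ")))
  if (nrow(tr) && length(setdiff(unique(spikes$session_id),
                                 unlist(strsplit(ucsv$session_id, ";")))) &&
      nrow(spikes))
    problems <- c(problems, "spikes.csv session ids absent from units.csv")
  if (length(problems))
    stop("invalid bundle at ", path, ":\n  ",
         paste(problems, collapse = "\n  "))
  wfCols <- grep("^wf_", names(ucsv), value = TRUE)
  units <- lapply(seq_len(nrow(ucsv)), function(i) {
    wf <- as.numeric(ucsv[i, wfCols])
    wf <- wf[!is.na(wf)]
    truth <- list()
    if ("true_class" %in% names(ucsv) && !is.na(ucsv$true_class[i]))
      truth <- list(klass = ucsv$true_class[i], a = ucsv$true_a[i],
                    isRamping = as.logical(ucsv$true_is_ramping[i]))
    new("SpikeUnit",
        unitId = ucsv$unit_id[i], sessionId = ucsv$session_id[i],
        animalId = if ("animal_id" %in% names(ucsv)) ucsv$animal_id[i]
                   else NA_character_,
        spikeTimes = sort(spikes$spike_time_s[spikes$unit_id ==
                                                ucsv$unit_id[i]]),
        waveform = wf, samplingRate = ucsv$sampling_rate_hz[i],
        meanRate = ucsv$mean_rate_hz[i], truth = truth)
  })
  cfgList <- yaml::read_yaml(file.path(path, "config.yaml"))
  cfg <- if (length(cfgList)) .configFromList(cfgList) else NULL
  new("FiSession", trials = tr, units = units, config = cfg)
}
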