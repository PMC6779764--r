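#' @include AllClasses.R
NULL

## Nakagawa-style R2 for a Gaussian mixed model: fixed-effect variance over
## (fixed + random-intercept + residual) variance; conditional adds the
## random component to the numerator.
.r2Mixed <- function(fit) {
  vf <- var(as.numeric(model.matrix(fit) %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)
  vr <- sum(vapply(vc, function(m) sum(diag(m)), numeric(1)))
  ve <- attr(vc, "sc")^2
  c(marginal = vf / (vf + vr + ve),
    conditional = (vf + vr) / (vf + vr + ve))
}

.lrVsNull <- function(data, fullForm, nullForm, group) {
  full <- suppressMessages(suppressWarnings(
    lme4::lmer(fullForm, data = data, REML = FALSE)))
  null <- suppressMessages(suppressWarnings(
    lme4::lmer(nullForm, data = data, REML = FALSE)))
  stat <- as.numeric(2 * (logLik(full) - logLik(null)))
  df <- attr(logLik(full), "df") - attr(logLik(null), "df")
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

.reportTerms <- function(a) {
  data.frame(term = rownames(a),
             F = a[, "F value"],
             df1 = a[, "NumDF"],
             df2 = a[, "DenDF"],
             p = a[, "Pr(>F)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

.mixedReport <- function(formula, terms, n, r2, lr, note = NULL) {
  structure(list(formula = formula, terms = terms, n_observations = n,
                 r2_marginal = unname(r2["marginal"]),
                 r2_conditional = unname(r2["conditional"]),
                 lr_vs_null = lr, note = note),
            class = "MixedModelReport")
}

#' @export
print.MixedModelReport <- function(x, ...) {
  cat("Mixed-model report:", x$formula, "\n")
  cat("Observations:", x$n_observations,
      " R2 (marginal):", signif(x$r2_marginal, 2),
      " R2 (conditional):", signif(x$r2_conditional, 2), "\n")
  tt <- x$terms
  tt$F <- signif(tt$F, 3)
  tt$p <- signif(tt$p, 2)
  print(tt, row.names = FALSE)
  if (!is.null(x$lr_vs_null))
    cat(sprintf("vs. null model: LR = %.3g (df %d), p = %.3g\n",
                x$lr_vs_null$statistic, x$lr_vs_null$df, x$lr_vs_null$p))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

.condFactors <- function(d) {
  d$stim <- factor(d$stim, levels = intersect(.STIM_LEVELS, unique(d$stim)))
  d$drug <- factor(d$drug, levels = intersect(.DRUG_LEVELS, unique(d$drug)))
  d
}

#' Mixed-effects model of response times
#'
#' Fits \code{RT ~ Stim * Drug + (1 | Animal)}: response time as a
#' function of the stimulation condition (NoStim / 2 Hz / 20 Hz), drug
#' (saline / muscimol) and their interaction, with a random intercept per
#' animal.  Term-wise F tests use Satterthwaite denominator degrees of
#' freedom on sum-to-zero contrasts (type III); the likelihood-ratio test
#' compares maximum-likelihood refits of the full model against the
#' intercept-plus-random-intercept null.  With a single animal the random
#' effect is degenerate and the function falls back to a fixed-effects
#' model with a loud warning.
#'
#' @param trials trial table; rows with a \code{virus} column can be
#'   pre-filtered by the caller to model opsin and control groups
#'   separately.
#' @param granularity "per_press" models every press in the interval
#'   (response times of all presses); "per_trial" models one latency per
#'   trial (the rewarded press, i.e. first press after the interval).
#' @param interval fixed interval, seconds.
#' @param lr compute the likelihood-ratio test vs. the null (two extra ML
#'   fits); disable in tight simulation loops.
#' @return a \code{MixedModelReport}: term table (F, df, p) in the order
#'   main effects, two-way interaction; observation count;
#'   marginal/conditional R-squared; LR vs. null.
#' @export
fitRtModel <- function(trials, granularity = c("per_press", "per_trial"),
                       interval = 12, lr = TRUE) {
  granularity <- match.arg(granularity)
  stopifnot(nrow(trials) > 0)
  if (granularity == "per_press") {
    reps <- lapply(trials$response_times, function(x)
      x[x >= 0 & x <= interval])
    n <- lengths(reps)
    d <- data.frame(rt = unlist(reps),
                    animal_id = rep(trials$animal_id, n),
                    stim = rep(trials$stim, n),
                    drug = rep(trials$drug, n),
                    stringsAsFactors = FALSE)
  } else {
    d <- data.frame(rt = trials$reward_time_s,
                    animal_id = trials$animal_id,
                    stim = trials$stim, drug = trials$drug,
                    stringsAsFactors = FALSE)
    d <- d[!is.na(d$rt), ]
  }
  d <- .condFactors(d)
  if (nlevels(d$drug) < 2 || nlevels(d$stim) < 2)
    stop("need at least two drug and two stim levels to fit the model")
  contr <- list(stim = "contr.sum", drug = "contr.sum")
  if (length(unique(d$animal_id)) < 2L) {
    warning("single animal: random intercept degenerate; ",
            "falling back to a fixed-effects model", immediate. = TRUE)
    fit <- lm(rt ~ stim * drug, data = d, contrasts = contr)
    a <- car::Anova(fit, type = 3)
    terms <- data.frame(term = rownames(a), F = a[, "F value"],
                        df1 = a[, "Df"], df2 = fit$df.residual,
                        p = a[, "Pr(>F)"], row.names = NULL,
                        stringsAsFactors = FALSE)
    terms <- terms[!terms$term %in% c("(Intercept)", "Residuals"), ]
    r2 <- c(marginal = summary(fit)$r.squared,
            conditional = summary(fit)$r.squared)
    lrRes <- if (lr) {
      nullFit <- lm(rt ~ 1, data = d)
      stat <- as.numeric(2 * (logLik(fit) - logLik(nullFit)))
      df <- attr(logLik(fit), "df") - attr(logLik(nullFit), "df")
      list(statistic = stat, df = df,
           p = pchisq(stat, df, lower.tail = FALSE))
    }
    return(.mixedReport("RT ~ Stim * Drug (fixed effects only)", terms,
                        nrow(d), r2, lrRes,
                        note = "single animal: no random intercept"))
  }
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(rt ~ stim * drug + (1 | animal_id), data = d,
                   contrasts = contr)))
  a <- suppressMessages(anova(fit, type = 3))
  lrRes <- if (lr)
    .lrVsNull(d, rt ~ stim * drug + (1 | animal_id),
              rt ~ 1 + (1 | animal_id))
  .mixedReport("RT ~ Stim * Drug + (1 | Animal)", .reportTerms(a),
               nrow(d), .r2Mixed(fit), lrRes)
}

#' Long firing-rate table for the population model
#'
#' Bins every unit's firing within every trial of its animal and stacks
#' the result as one long table of unsmoothed, unnormalized rates, the
#' input to \code{\link{fitFrModel}}.
#'
#' @param units list of \linkS4class{SpikeUnit}.
#' @param trials trial table.
#' @param bin bin width, seconds.  10-ms bins reproduce the headline model
#'   structure; coarser bins (e.g. 0.1-0.5 s) keep desk-scale fits small.
#'   A message reports the row count when it exceeds 2e6.
#' @param interval fixed interval, seconds.
#' @return data.frame: unit_id, animal_id, drug, stim, trial_index,
#'   time_s (bin centre), rate (spikes/s).
#' @export
frTable <- function(units, trials, bin = 0.1, interval = 12) {
  nb <- as.integer(round(interval / bin))
  est <- length(units) * nb * nrow(trials) / max(1L, length(unique(trials$animal_id)))
  if (est > 2e6)
    message(sprintf("frTable: ~%.1fM rows at %g-ms bins; consider coarser bins",
                    est / 1e6, bin * 1000))
  out <- vector("list", length(units))
  for (i in seq_along(units)) {
    u <- units[[i]]
    tr <- trials[trials$session_id == u@sessionId, ]
    if (!nrow(tr)) next
    counts <- binFiring(u, tr, bin, interval)
    centers <- as.numeric(colnames(counts))
    out[[i]] <- data.frame(
      unit_id = u@unitId,
      animal_id = u@animalId,
      drug = rep(tr$drug, times = nb),
      stim = rep(tr$stim, times = nb),
      trial_index = rep(tr$trial_index, times = nb),
      time_s = rep(centers, each = nrow(tr)),
      rate = as.vector(counts) / bin,
      stringsAsFactors = FALSE)
  }
  .rbindRows(out)
}

#' Mixed-effects model of population firing rate
#'
#' Fits \code{FR ~ Time * Stim * Drug + (1 | Neuron)}: binned firing rate
#' as a function of time in the interval (continuous bin-centre
#' covariate), stimulation condition, drug, all interactions, and a random
#' intercept per neuron.  The term table is ordered main effects, two-way,
#' three-way; the three-way Time:Stim:Drug term is the signature of
#' condition-dependent ramping.
#'
#' @param fr long table from \code{\link{frTable}}.
#' @param lr compute the likelihood-ratio test vs. the
#'   intercept-plus-random-intercept null.
#' @return a \code{MixedModelReport}.
#' @export
fitFrModel <- function(fr, lr = TRUE) {
  stopifnot(all(c("unit_id", "time_s", "stim", "drug", "rate") %in% names(fr)))
  d <- .condFactors(fr)
  contr <- list(stim = "contr.sum", drug = "contr.sum")
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(rate ~ time_s * stim * drug + (1 | unit_id), data = d,
                   contrasts = contr)))
  a <- suppressMessages(anova(fit, type = 3))
  terms <- .reportTerms(a)
  want <- c("time_s", "stim", "drug", "time_s:stim", "time_s:drug",
            "stim:drug", "time_s:stim:drug")
  terms <- terms[match(intersect(want, terms$term), terms$term), ]
  lrRes <- if (lr)
    .lrVsNull(d, rate ~ time_s * stim * drug + (1 | unit_id),
              rate ~ 1 + (1 | unit_id))
  .mixedReport("FR ~ Time * Stim * Drug + (1 | Neuron)", terms,
               nrow(d), .r2Mixed(fit), lrRes)
}

#' Paired comparison with effect size
#'
#' Paired t test of two equal-length condition vectors (e.g. per-animal
#' curvature under two stimulation conditions) with Cohen's d computed on
#' the paired differences, plus group means and SEMs.
#'
#' @param a,b paired numeric vectors.
#' @param labels length-2 labels for the two groups.
#' @return list: labels, n, mean_a, sem_a, mean_b, sem_b, t, df, p, d,
#'   zero_variance.  Zero-variance non-zero differences yield a signed
#'   infinite t and d with \code{zero_variance = TRUE}; identical vectors
#'   yield t = 0, p = 1, d = 0.
#' @examples
#' pairedComparison(c(0.25, 0.30, 0.22), c(0.12, 0.18, 0.10),
#'                  labels = c("saline", "muscimol"))
#' @export
pairedComparison <- function(a, b, labels = c("a", "b")) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  keep <- complete.cases(a, b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2L) stop("fewer than 2 complete pairs")
  diffs <- a - b
  sem <- function(x) sd(x) / sqrt(length(x))
  base <- list(labels = labels, n = n,
               mean_a = mean(a), sem_a = sem(a),
               mean_b = mean(b), sem_b = sem(b))
  if (sd(diffs) == 0) {
    if (all(diffs == 0))
      return(c(base, list(t = 0, df = n - 1L, p = 1, d = 0,
                          zero_variance = FALSE)))
    s <- sign(mean(diffs))
    return(c(base, list(t = s * Inf, df = n - 1L, p = 0, d = s * Inf,
                        zero_variance = TRUE)))
  }
  tt <- t.test(a, b, paired = TRUE)
  c(base, list(t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, d = mean(diffs) / sd(diffs),
               zero_variance = FALSE))
}
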