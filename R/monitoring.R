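#' Score a synthetic batch against a real reference set
#'
#' Each synthetic sequence receives its best-match score against the real
#' set: the maximum over real sequences of the channel-averaged similarity
#' under the configured metric (calibrated GAK on PSDs, cosine on PSDs, or
#' cosine in the time domain).
#'
#' @param real non-empty reference \linkS4class{SequenceSet}.
#' @param synthetic non-empty \linkS4class{SequenceSet} with the same
#'   channel geometry.
#' @param config a \linkS4class{MonitorConfig}.
#' @return List with \code{scores} (one per synthetic sequence),
#'   \code{mean}, \code{sd} and \code{in_range_fraction} (fraction of
#'   scores inside the calibration's acceptance range; NA for cosine
#'   metrics).
#' @export
scoreBatch <- function(real, synthetic, config) {
    stopifnot(is(config, "MonitorConfig"))
    if (nSequences(real) == 0L || nSequences(synthetic) == 0L)
        stopf("real and synthetic sets must be non-empty",
              class = "coptgak_input_error")
    if (!identical(channelNames(real), channelNames(synthetic)) ||
        seqLength(sequences(real)[[1]]) != seqLength(sequences(synthetic)[[1]]))
        stopf("channel geometry mismatch between real and synthetic sets",
              class = "coptgak_validation_error")
    pm <- switch(config@metric,
        copt_gak = pairwiseScoreMatrix(synthetic, real, metric = "gak",
                                       domain = "psd",
                                       sigma = sigmaOpt(config@calibration),
                                       welch = config@welch),
        cosine_psd = pairwiseScoreMatrix(synthetic, real, metric = "cosine",
                                         domain = "psd", welch = config@welch),
        cosine_time = pairwiseScoreMatrix(synthetic, real, metric = "cosine",
                                          domain = "time"))
    sc <- apply(pm$scores, 1L, max)
    frac <- NA_real_
    if (config@metric == "copt_gak") {
        ar <- acceptanceRange(config@calibration)
        frac <- inRangeFraction(sc, ar)
    }
    list(scores = sc, mean = mean(sc),
         sd = if (length(sc) > 1L) stats::sd(sc) else 0,
         in_range_fraction = frac)
}

#' Fraction of scores inside a range
#'
#' @param scores numeric vector.
#' @param range numeric pair (lo, hi); endpoints inclusive.
#' @return Fraction in [0, 1].
#' @export
inRangeFraction <- function(scores, range) {
    mean(scores >= range[1] & scores <= range[2])
}

#' Training stop rule (pure trace function)
#'
#' Decides, from a checkpoint trace alone, where the training monitor
#' stops.  For the cosine metrics the rule tracks the running maximum of
#' the mean score and fires after \code{patience} consecutive checkpoints
#' fail to exceed it.  For the calibrated GAK the rule fires at the first
#' checkpoint where the in-range fraction reaches \code{minFraction} and
#' the same held at the immediately preceding checkpoint.
#'
#' @param steps checkpoint epochs (strictly increasing).
#' @param means mean batch score per checkpoint.
#' @param fractions in-range fraction per checkpoint (calibrated-GAK rule).
#' @param metric \code{"copt_gak"}, \code{"cosine_psd"} or
#'   \code{"cosine_time"}.
#' @param patience consecutive non-improving checkpoints required (cosine).
#' @param minFraction in-range fraction threshold (calibrated GAK).
#' @return List with \code{stop_index} (index into \code{steps}, or NA) and
#'   \code{reason}.
#' @export
applyTrainingRule <- function(steps, means, fractions = NULL,
                              metric = "cosine_psd", patience = 2L,
                              minFraction = 0.25) {
    n <- length(steps)
    if (metric == "copt_gak") {
        ok <- fractions >= minFraction
        for (i in seq_len(n))
            if (i >= 2L && ok[i] && ok[i - 1L])
                return(list(stop_index = i, reason = "in_range_rule"))
        return(list(stop_index = NA_integer_, reason = "horizon_reached"))
    }
    runmax <- -Inf; fails <- 0L
    for (i in seq_len(n)) {
        if (means[i] > runmax) {
            runmax <- means[i]; fails <- 0L
        } else {
            fails <- fails + 1L
            if (fails >= patience)
                return(list(stop_index = i, reason = "local_max_patience"))
        }
    }
    list(stop_index = NA_integer_, reason = "horizon_reached")
}

#' Denoising stop rule (pure trace function)
#'
#' Fires when the mean score strictly decreases at two consecutive
#' monitored steps (each relative to the immediately preceding monitored
#' value).
#'
#' @param steps monitored denoising steps (strictly increasing).
#' @param means mean batch score per monitored step.
#' @return List with \code{stop_index} (or NA) and \code{reason}.
#' @export
applyDenoisingRule <- function(steps, means) {
    n <- length(steps)
    if (n >= 3L) for (i in 3L:n)
        if (means[i] < means[i - 1L] && means[i - 1L] < means[i - 2L])
            return(list(stop_index = i, reason = "two_consecutive_drops"))
    list(stop_index = NA_integer_, reason = "horizon_reached")
}

best_index <- function(means) which.max(means)  # ties -> earliest

make_trace <- function(steps, means, sds, fracs, scores, stop_index, reason,
                       seed = NA_integer_) {
    keep <- if (is.na(stop_index)) seq_along(steps) else seq_len(stop_index)
    cp <- data.frame(step = as.integer(steps[keep]), mean = means[keep],
                     sd = sds[keep], in_range_fraction = fracs[keep])
    stop_step <- if (is.na(stop_index)) NA_integer_
                 else as.integer(steps[stop_index])
    new("MonitorTrace", checkpoints = cp, scores = scores[keep],
        stopStep = stop_step,
        bestStep = as.integer(steps[best_index(means[keep])]),
        stopReason = reason, seed = as.integer(seed))
}

#' Monitor the training of a generative model and stop it early
#'
#' Evaluates the model every \code{epochInterval} epochs by scoring a
#' batch of synthetic sequences (obtained from \code{generator}) against
#' the real training set, and applies \code{\link{applyTrainingRule}}.
#' The generator is never queried at epochs that are not multiples of the
#' interval — checkpoint evaluation is assumed expensive.
#'
#' @param generator \code{function(epoch)} returning a
#'   \linkS4class{SequenceSet} of synthetic sequences for the model state
#'   at that epoch.
#' @param real the real training \linkS4class{SequenceSet}.
#' @param config a \linkS4class{MonitorConfig}.
#' @param seed RNG seed recorded in the trace (the generator is expected
#'   to derive its batch randomness from it).
#' @return A \linkS4class{MonitorTrace}.  If the generator throws, the
#'   partial trace is returned with \code{stopReason = "aborted"}.
#' @export
trainingMonitor <- function(generator, real, config, seed = NA_integer_) {
    stopifnot(is(config, "MonitorConfig"))
    epochs <- seq.int(config@epochInterval, config@maxEpochs,
                      by = config@epochInterval)
    steps <- integer(); means <- sds <- fracs <- numeric(); scores <- list()
    for (ep in epochs) {
        sb <- tryCatch({
            synth <- generator(ep)
            scoreBatch(real, synth, config)
        }, error = function(e) e)
        if (inherits(sb, "error")) {
            cklog("error", "monitor", sprintf(
                "generator failed at epoch %d: %s; aborting with partial trace",
                ep, conditionMessage(sb)))
            if (length(steps) == 0L)
                stopf("generator failed at first checkpoint: %s",
                      conditionMessage(sb), class = "coptgak_input_error")
            return(make_trace(steps, means, sds, fracs, scores,
                              NA_integer_, "aborted", seed))
        }
        steps <- c(steps, ep); means <- c(means, sb$mean)
        sds <- c(sds, sb$sd); fracs <- c(fracs, sb$in_range_fraction)
        scores <- c(scores, list(sb$scores))
        cklog("info", "monitor", sprintf(
            "epoch %d: mean=%.4f sd=%.4f in_range=%s", ep, sb$mean, sb$sd,
            ifelse(is.na(sb$in_range_fraction), "NA",
                   sprintf("%.2f", sb$in_range_fraction))))
        dec <- applyTrainingRule(steps, means, fracs, config@metric,
                                 config@patienceChecks, config@inRangeFraction)
        if (!is.na(dec$stop_index)) {
            cklog("info", "monitor", sprintf("stopping at epoch %d (%s)",
                                             ep, dec$reason))
            return(make_trace(steps, means, sds, fracs, scores,
                              dec$stop_index, dec$reason, seed))
        }
    }
    make_trace(steps, means, sds, fracs, scores, NA_integer_,
               "horizon_reached", seed)
}

#' Monitor a denoising (sampling) run and stop it early
#'
#' Scores the intermediate batch every \code{denoiseInterval} steps and
#' applies \code{\link{applyDenoisingRule}} (stop after two consecutive
#' drops of the mean score).  Returns the batch from the best
#' (maximal-mean) monitored step.
#'
#' @param sampler \code{function(step)} returning the intermediate batch
#'   (a \linkS4class{SequenceSet}) at that denoising step, or NULL if the
#'   sampler is exhausted.
#' @param real the real training \linkS4class{SequenceSet}.
#' @param config a \linkS4class{MonitorConfig}.
#' @param seed RNG seed recorded in the trace.
#' @return List with \code{trace} (a \linkS4class{MonitorTrace}) and
#'   \code{batch} (the best-step \linkS4class{SequenceSet}).
#' @export
denoisingMonitor <- function(sampler, real, config, seed = NA_integer_) {
    stopifnot(is(config, "MonitorConfig"))
    msteps <- seq.int(config@denoiseInterval, config@denoiseSteps,
                      by = config@denoiseInterval)
    if (msteps[length(msteps)] != config@denoiseSteps)
        msteps <- c(msteps, config@denoiseSteps)   # final step always checked
    steps <- integer(); means <- sds <- fracs <- numeric(); scores <- list()
    best_batch <- NULL; best_mean <- -Inf
    for (st in msteps) {
        batch <- sampler(st)
        if (is.null(batch)) break                   # exhausted -> horizon
        sb <- scoreBatch(real, batch, config)
        steps <- c(steps, st); means <- c(means, sb$mean)
        sds <- c(sds, sb$sd); fracs <- c(fracs, sb$in_range_fraction)
        scores <- c(scores, list(sb$scores))
        if (sb$mean > best_mean) { best_mean <- sb$mean; best_batch <- batch }
        cklog("info", "monitor", sprintf("denoise step %d: mean=%.4f sd=%.4f",
                                         st, sb$mean, sb$sd))
        dec <- applyDenoisingRule(steps, means)
        if (!is.na(dec$stop_index)) {
            cklog("info", "monitor",
                  sprintf("stopping denoising at step %d (%s)", st, dec$reason))
            return(list(trace = make_trace(steps, means, sds, fracs, scores,
                                           dec$stop_index, dec$reason, seed),
                        batch = best_batch))
        }
    }
    list(trace = make_trace(steps, means, sds, fracs, scores, NA_integer_,
                            "horizon_reached", seed),
         batch = best_batch)
}
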