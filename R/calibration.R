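#' Default bandwidth grid and standard-deviation presets
#'
#' The calibration searches a log-spaced grid of bandwidths; 60 points
#' between 1e-3 and 10 cover the range from median-heuristic selectivity
#' to near-saturation for standardized activity signals.
#'
#' @param n number of grid points.
#' @param from,to grid endpoints.
#' @return Sorted positive numeric vector.
#' @export
sigmaGridDefault <- function(n = 60L, from = 1e-3, to = 10) {
    exp(seq(log(from), log(to), length.out = n))
}

#' @rdname sigmaGridDefault
#' @param preset \code{"sd1"} = [0.01, 0.03] (tight; most generous scores),
#'   \code{"sd2"} = [0.09, 0.12] (default), \code{"sd3"} = [0.18, 0.22].
#' @return \code{stdRangePreset}: numeric pair (lo, hi).
#' @export
stdRangePreset <- function(preset = c("sd2", "sd1", "sd3")) {
    preset <- match.arg(preset)
    switch(preset,
           sd1 = c(0.01, 0.03),
           sd2 = c(0.09, 0.12),
           sd3 = c(0.18, 0.22))
}

#' Sweep the GAK bandwidth over a grid and record score statistics
#'
#' For each bandwidth on the grid the normalized, channel-averaged GAK
#' score is computed between the train and validation sets (on Welch PSDs
#' by default) and summarized by mean and standard deviation.  Two pair
#' populations are supported: \code{"best_match"} (for each training
#' sequence, its maximum score over the validation set — the statistics of
#' the most similar sequences) and \code{"all_pairs"} (every train x
#' validation pair).
#'
#' @param train,val non-empty \linkS4class{SequenceSet}s of the same class.
#' @param sigmaGrid sorted positive bandwidth grid.
#' @param aggregation \code{"best_match"} (default) or \code{"all_pairs"}.
#' @param domain \code{"psd"} (default) or \code{"time"}.
#' @param welch \linkS4class{WelchConfig} for the PSD domain.
#' @return data.frame with columns \code{sigma}, \code{mean}, \code{sd}.
#' @export
sigmaSweep <- function(train, val, sigmaGrid = sigmaGridDefault(),
                       aggregation = c("best_match", "all_pairs"),
                       domain = c("psd", "time"), welch = WelchConfig()) {
    aggregation <- match.arg(aggregation); domain <- match.arg(domain)
    if (length(sigmaGrid) == 0L)
        stopf("empty sigma grid", class = "coptgak_config_error")
    if (any(sigmaGrid <= 0))
        stopf("sigma grid must be strictly positive",
              class = "coptgak_config_error")
    if (nSequences(train) == 0L || nSequences(val) == 0L)
        stopf("train and validation sets must be non-empty",
              class = "coptgak_input_error")
    matsT <- domain_matrices(train, domain, welch)
    matsV <- domain_matrices(val, domain, welch)
    res <- lapply(sigmaGrid, function(sg) {
        sc <- gak_score_matrix_from_mats(matsT, matsV, sg)
        v <- if (aggregation == "best_match") apply(sc, 1L, max) else as.vector(sc)
        c(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0)
    })
    out <- data.frame(sigma = sigmaGrid,
                      mean = vapply(res, `[[`, numeric(1), "mean"),
                      sd = vapply(res, `[[`, numeric(1), "sd"))
    out
}

#' Class-optimized GAK bandwidth selection
#'
#' The core calibration: among grid bandwidths whose train-validation
#' score standard deviation lies inside \code{stdRange}, select the one
#' maximizing the mean score (ties broken toward the smaller bandwidth).
#' The acceptance range used later by the training monitor is the mean
#' plus/minus one standard deviation at the optimum, clipped to [0, 1]
#' (or one-sided, lower bound only, when \code{rangeMode = "one_sided"}).
#'
#' @inheritParams sigmaSweep
#' @param stdRange feasibility interval for the score standard deviation;
#'   default [0.09, 0.12] (see \code{\link{stdRangePreset}}).
#' @param rangeMode \code{"two_sided"} (default) or \code{"one_sided"}.
#' @param classLabel,subjectScope identifiers recorded in the result.
#' @return A \linkS4class{GAKCalibration} (with the full sweep retained).
#'   If no grid point is feasible, an error of class
#'   \code{"coptgak_no_feasible_sigma"} is signalled whose condition
#'   carries the sweep in \code{$sweep} so the caller can widen the grid
#'   or the range.
#' @export
optimizeSigma <- function(train, val, sigmaGrid = sigmaGridDefault(),
                          stdRange = stdRangePreset("sd2"),
                          aggregation = c("best_match", "all_pairs"),
                          domain = c("psd", "time"), welch = WelchConfig(),
                          rangeMode = c("two_sided", "one_sided"),
                          classLabel = "all", subjectScope = "all") {
    aggregation <- match.arg(aggregation); domain <- match.arg(domain)
    rangeMode <- match.arg(rangeMode)
    if (length(stdRange) != 2L || stdRange[1] >= stdRange[2])
        stopf("stdRange must be an increasing pair",
              class = "coptgak_config_error")
    sw <- sigmaSweep(train, val, sigmaGrid, aggregation, domain, welch)
    sw$feasible <- sw$sd >= stdRange[1] & sw$sd <= stdRange[2]
    if (!any(sw$feasible)) {
        cond <- errorCondition(
            sprintf("no grid bandwidth meets sd constraint [%g, %g]; sd spans [%g, %g]",
                    stdRange[1], stdRange[2], min(sw$sd), max(sw$sd)),
            class = c("coptgak_no_feasible_sigma", "coptgak_error", "error",
                      "condition"))
        cond$sweep <- sw
        stop(cond)
    }
    feas <- sw[sw$feasible, ]
    best <- feas[which.max(feas$mean), ]   # which.max: lowest index on ties,
                                           # grid sorted => smaller sigma
    ar <- if (rangeMode == "two_sided")
        c(max(0, best$mean - best$sd), min(1, best$mean + best$sd))
    else c(max(0, best$mean - best$sd), 1)
    cklog("info", "calibration",
          sprintf("class=%s sigma_opt=%.5g mean=%.4f sd=%.4f",
                  classLabel, best$sigma, best$mean, best$sd))
    new("GAKCalibration", sigmaOpt = best$sigma, meanScore = best$mean,
        stdScore = best$sd, stdRange = as.numeric(stdRange),
        acceptanceRange = ar, sweep = sw, aggregation = aggregation,
        classLabel = classLabel, subjectScope = subjectScope)
}

#' Per-class calibration
#'
#' Runs \code{\link{optimizeSigma}} independently on the class-filtered
#' subsets: each activity class needs its own bandwidth to satisfy the
#' standard-deviation constraint.
#'
#' @inheritParams optimizeSigma
#' @param classes class labels to calibrate; default: all classes present
#'   in the training set.
#' @return Named list of \linkS4class{GAKCalibration}, one per class.
#' @export
calibratePerClass <- function(train, val, classes = NULL,
                              sigmaGrid = sigmaGridDefault(),
                              stdRange = stdRangePreset("sd2"),
                              aggregation = c("best_match", "all_pairs"),
                              domain = c("psd", "time"),
                              welch = WelchConfig(),
                              rangeMode = c("two_sided", "one_sided")) {
    aggregation <- match.arg(aggregation); domain <- match.arg(domain)
    rangeMode <- match.arg(rangeMode)
    if (is.null(classes)) classes <- unique(classLabels(train))
    out <- lapply(classes, function(cl) {
        tr <- filterClass(train, cl)    # errors if absent, naming the class
        va <- filterClass(val, cl)
        optimizeSigma(tr, va, sigmaGrid, stdRange, aggregation, domain,
                      welch, rangeMode, classLabel = cl)
    })
    names(out) <- classes
    out
}
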