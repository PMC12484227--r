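#' RunConfig: one object holding every pipeline constant
#'
#' Mirrors the YAML configuration consumed by the command-line interface
#' field-for-field.  Defaults are the study's operating point: 160-sample
#' windows with overlap 40 at 50 Hz, STFT 22/20, Welch 64/32, a 60-point
#' log bandwidth grid on [1e-3, 10], and the standard-deviation constraint
#' [0.09, 0.12].
#'
#' @slot windowWidth,windowOverlap segmentation of long recordings.
#' @slot stftWindow,stftOverlap STFT geometry.
#' @slot welchWindow,welchOverlap Welch PSD geometry.
#' @slot sigmaGrid sorted positive bandwidth grid.
#' @slot stdRange feasibility interval for the calibration.
#' @slot epochInterval,maxEpochs,syntheticBatch,patienceChecks monitor
#'   settings.
#' @slot inRangeFraction,denoiseSteps,denoiseInterval monitor settings.
#' @slot randomSeed base RNG seed.
#' @export
setClass("RunConfig",
    representation(windowWidth = "integer", windowOverlap = "integer",
                   stftWindow = "integer", stftOverlap = "integer",
                   welchWindow = "integer", welchOverlap = "integer",
                   sigmaGrid = "numeric", stdRange = "numeric",
                   epochInterval = "integer", maxEpochs = "integer",
                   syntheticBatch = "integer", patienceChecks = "integer",
                   inRangeFraction = "numeric", denoiseSteps = "integer",
                   denoiseInterval = "integer", randomSeed = "integer"))

setValidity("RunConfig", function(object) {
    pairs <- list(c(object@windowOverlap, object@windowWidth),
                  c(object@stftOverlap, object@stftWindow),
                  c(object@welchOverlap, object@welchWindow))
    for (p in pairs)
        if (p[1] < 0L || p[1] >= p[2])
            return("every overlap must satisfy 0 <= overlap < width")
    if (length(object@stdRange) != 2L ||
        object@stdRange[1] >= object@stdRange[2])
        return("stdRange lower bound must be < upper bound")
    g <- object@sigmaGrid
    if (any(g <= 0) || is.unsorted(g, strictly = TRUE))
        return("sigmaGrid must be strictly positive and sorted")
    TRUE
})

#' @rdname RunConfig-class
#' @param windowWidth,windowOverlap,stftWindow,stftOverlap see slots.
#' @param welchWindow,welchOverlap,sigmaGrid,stdRange see slots.
#' @param epochInterval,maxEpochs,syntheticBatch,patienceChecks see slots.
#' @param inRangeFraction,denoiseSteps,denoiseInterval,randomSeed see slots.
#' @return A \linkS4class{RunConfig}.
#' @export
RunConfig <- function(windowWidth = 160L, windowOverlap = 40L,
                      stftWindow = 22L, stftOverlap = 20L,
                      welchWindow = 64L, welchOverlap = 32L,
                      sigmaGrid = sigmaGridDefault(),
                      stdRange = stdRangePreset("sd2"),
                      epochInterval = 50L, maxEpochs = 4500L,
                      syntheticBatch = 128L, patienceChecks = 2L,
                      inRangeFraction = 0.25, denoiseSteps = 3000L,
                      denoiseInterval = 30L, randomSeed = 1L) {
    new("RunConfig", windowWidth = as.integer(windowWidth),
        windowOverlap = as.integer(windowOverlap),
        stftWindow = as.integer(stftWindow),
        stftOverlap = as.integer(stftOverlap),
        welchWindow = as.integer(welchWindow),
        welchOverlap = as.integer(welchOverlap),
        sigmaGrid = sigmaGrid, stdRange = stdRange,
        epochInterval = as.integer(epochInterval),
        maxEpochs = as.integer(maxEpochs),
        syntheticBatch = as.integer(syntheticBatch),
        patienceChecks = as.integer(patienceChecks),
        inRangeFraction = inRangeFraction,
        denoiseSteps = as.integer(denoiseSteps),
        denoiseInterval = as.integer(denoiseInterval),
        randomSeed = as.integer(randomSeed))
}

#' Read/write a RunConfig as YAML
#'
#' Field names in the YAML are snake_case versions of the slots
#' (\code{window_width}, \code{std_range}, ...); omitted fields keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return \code{readRunConfig}: a \linkS4class{RunConfig}.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path))
        stopf("config file not found: %s", path, class = "coptgak_input_error")
    y <- yaml::read_yaml(path)
    args <- list()
    map <- c(window_width = "windowWidth", window_overlap = "windowOverlap",
             stft_window = "stftWindow", stft_overlap = "stftOverlap",
             welch_window = "welchWindow", welch_overlap = "welchOverlap",
             sigma_grid = "sigmaGrid", std_range = "stdRange",
             epoch_interval = "epochInterval", max_epochs = "maxEpochs",
             synthetic_batch = "syntheticBatch",
             patience_checks = "patienceChecks",
             in_range_fraction = "inRangeFraction",
             denoise_steps = "denoiseSteps",
             denoise_interval = "denoiseInterval", random_seed = "randomSeed")
    for (k in names(y)) {
        if (!k %in% names(map))
            stopf("unknown config key '%s'", k, class = "coptgak_config_error")
        args[[map[[k]]]] <- if (map[[k]] %in% c("sigmaGrid", "stdRange",
                                                "inRangeFraction"))
            as.numeric(unlist(y[[k]])) else unlist(y[[k]])
    }
    do.call(RunConfig, args)
}

#' @rdname readRunConfig
#' @param config a \linkS4class{RunConfig}.
#' @return \code{writeRunConfig}: \code{path}, invisibly.
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(list(
        window_width = config@windowWidth,
        window_overlap = config@windowOverlap,
        stft_window = config@stftWindow, stft_overlap = config@stftOverlap,
        welch_window = config@welchWindow,
        welch_overlap = config@welchOverlap,
        sigma_grid = config@sigmaGrid, std_range = config@stdRange,
        epoch_interval = config@epochInterval, max_epochs = config@maxEpochs,
        synthetic_batch = config@syntheticBatch,
        patience_checks = config@patienceChecks,
        in_range_fraction = config@inRangeFraction,
        denoise_steps = config@denoiseSteps,
        denoise_interval = config@denoiseInterval,
        random_seed = config@randomSeed), path)
    invisible(path)
}
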