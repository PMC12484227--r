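#' SensorSequence: one multichannel fixed-rate time-series window
#'
#' The atomic data object: a channels x timesteps matrix of uniformly
#' sampled sensor values (units arbitrary but consistent per channel),
#' together with the sample rate and class/subject labels.
#'
#' @slot values numeric matrix, channels x timesteps.
#' @slot sampleRate positive sampling rate in Hz.
#' @slot channelNames character vector, one per row of \code{values}.
#' @slot classLabel activity class label.
#' @slot subjectId participant/subject identifier.
#' @export
setClass("SensorSequence",
    representation(values = "matrix", sampleRate = "numeric",
                   channelNames = "character", classLabel = "character",
                   subjectId = "character"))

setValidity("SensorSequence", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be a numeric matrix")
    if (ncol(v) < 2L) return("sequence length must be >= 2")
    if (anyNA(v) || any(!is.finite(v))) return("values contain NA/non-finite entries")
    if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
        return("sampleRate must be a single positive number")
    if (length(object@channelNames) != nrow(v))
        return("channelNames length must equal the number of channels")
    if (length(object@classLabel) != 1L || length(object@subjectId) != 1L)
        return("classLabel and subjectId must be single strings")
    TRUE
})

#' Construct a SensorSequence
#'
#' @param values numeric matrix (channels x timesteps) or numeric vector
#'   (treated as one channel).
#' @param sampleRate sampling rate in Hz.
#' @param channelNames optional channel names; defaults to ch1..chK.
#' @param classLabel,subjectId labels (default \code{"unknown"}).
#' @return A \linkS4class{SensorSequence}.
#' @examples
#' s <- SensorSequence(matrix(rnorm(320), 2), sampleRate = 50)
#' nChannels(s); seqLength(s)
#' @export
SensorSequence <- function(values, sampleRate = 50,
                           channelNames = NULL,
                           classLabel = "unknown", subjectId = "unknown") {
    if (is.vector(values)) values <- matrix(values, nrow = 1L)
    if (is.null(channelNames))
        channelNames <- rownames(values) %||% paste0("ch", seq_len(nrow(values)))
    rownames(values) <- channelNames
    new("SensorSequence", values = values, sampleRate = as.numeric(sampleRate),
        channelNames = channelNames, classLabel = classLabel,
        subjectId = subjectId)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' SequenceSet: a labeled collection of SensorSequence windows
#'
#' All members share channel names, length and sample rate.  The
#' \code{role} records where the set sits in the pipeline
#' (train/validation/test/synthetic).
#'
#' @slot sequences list of \linkS4class{SensorSequence}.
#' @slot role one of \code{"train"}, \code{"validation"}, \code{"test"},
#'   \code{"synthetic"}.
#' @export
setClass("SequenceSet",
    representation(sequences = "list", role = "character"))

setValidity("SequenceSet", function(object) {
    if (!object@role %in% c("train", "validation", "test", "synthetic"))
        return("role must be train/validation/test/synthetic")
    sq <- object@sequences
    if (length(sq) == 0L) return(TRUE)  # empty allowed; scoring ops reject it
    ok <- vapply(sq, is, logical(1), "SensorSequence")
    if (!all(ok)) return("all elements must be SensorSequence objects")
    cn <- lapply(sq, slot, "channelNames")
    sr <- vapply(sq, slot, numeric(1), "sampleRate")
    if (!all(vapply(cn, identical, logical(1), cn[[1]])))
        return("all sequences must share channelNames")
    if (length(unique(sr)) != 1L)
        return("all sequences must share sampleRate")
    TRUE
})

#' Construct a SequenceSet
#'
#' @param sequences list of \linkS4class{SensorSequence}.
#' @param role pipeline role of the set.
#' @return A \linkS4class{SequenceSet}.
#' @export
SequenceSet <- function(sequences, role = c("train", "validation", "test",
                                            "synthetic")) {
    role <- match.arg(role)
    new("SequenceSet", sequences = sequences, role = role)
}

#' WelchConfig: parameters of the averaged-periodogram PSD estimator
#'
#' @slot subwindowLength segment length M (>= 2).
#' @slot overlap samples shared by consecutive segments (0 <= overlap < M).
#' @slot windowFunction taper identifier; \code{"hann"} (periodic) or
#'   \code{"rect"}.
#' @export
setClass("WelchConfig",
    representation(subwindowLength = "integer", overlap = "integer",
                   windowFunction = "character"))

setValidity("WelchConfig", function(object) {
    M <- object@subwindowLength
    if (M < 2L) return("subwindowLength must be >= 2")
    if (object@overlap < 0L || object@overlap >= M)
        return("overlap must satisfy 0 <= overlap < subwindowLength")
    if (!object@windowFunction %in% c("hann", "rect"))
        return("windowFunction must be 'hann' or 'rect'")
    TRUE
})

#' @rdname WelchConfig-class
#' @param subwindowLength,overlap,windowFunction see slots.
#' @return A \linkS4class{WelchConfig}.
#' @export
WelchConfig <- function(subwindowLength = 64L, overlap = 32L,
                        windowFunction = "hann") {
    new("WelchConfig", subwindowLength = as.integer(subwindowLength),
        overlap = as.integer(overlap), windowFunction = windowFunction)
}

#' PSDVector: per-channel Welch power spectral density of one window
#'
#' @slot power non-negative matrix, channels x frequency bins.
#' @slot frequencies one-sided Hz grid, monotone from 0.
#' @slot config the \linkS4class{WelchConfig} used.
#' @export
setClass("PSDVector",
    representation(power = "matrix", frequencies = "numeric",
                   config = "WelchConfig"))

setValidity("PSDVector", function(object) {
    if (any(object@power < -1e-12)) return("power must be non-negative")
    f <- object@frequencies
    if (length(f) != ncol(object@power))
        return("frequencies length must match power columns")
    if (f[1] != 0 || is.unsorted(f, strictly = TRUE))
        return("frequencies must increase strictly from 0")
    TRUE
})

#' SpectralSequence: STFT frames of one window
#'
#' @slot frames complex array, channels x frequency bins x time frames.
#' @slot stftWindow STFT segment length.
#' @slot stftOverlap samples shared by consecutive frames.
#' @slot windowFunction taper identifier.
#' @slot originalLength timesteps of the source window (for inversion).
#' @slot sampleRate sampling rate in Hz.
#' @slot channelNames channel identifiers.
#' @export
setClass("SpectralSequence",
    representation(frames = "array", stftWindow = "integer",
                   stftOverlap = "integer", windowFunction = "character",
                   originalLength = "integer", sampleRate = "numeric",
                   channelNames = "character"))

setValidity("SpectralSequence", function(object) {
    d <- dim(object@frames)
    if (length(d) != 3L) return("frames must be a 3D array")
    if (d[2] != object@stftWindow %/% 2L + 1L)
        return("frequency bin count must be floor(stftWindow/2)+1")
    if (object@stftOverlap >= object@stftWindow)
        return("stftOverlap must be < stftWindow")
    TRUE
})

#' GAKCalibration: a class-optimized GAK bandwidth and its score statistics
#'
#' Produced by \code{\link{optimizeSigma}}.  Holds the selected bandwidth
#' \code{sigmaOpt}, the train-validation score mean/sd at that bandwidth,
#' the acceptance range used by the training monitor, and the full sweep.
#'
#' @slot sigmaOpt selected bandwidth (positive).
#' @slot meanScore mean normalized GAK score at \code{sigmaOpt}.
#' @slot stdScore standard deviation of scores at \code{sigmaOpt}.
#' @slot stdRange the feasibility interval imposed on \code{stdScore}.
#' @slot acceptanceRange score interval used as the monitor's target range.
#' @slot sweep data.frame with columns sigma, mean, sd, feasible.
#' @slot aggregation \code{"best_match"} or \code{"all_pairs"}.
#' @slot classLabel,subjectScope identifiers of the calibrated subset.
#' @export
setClass("GAKCalibration",
    representation(sigmaOpt = "numeric", meanScore = "numeric",
                   stdScore = "numeric", stdRange = "numeric",
                   acceptanceRange = "numeric", sweep = "data.frame",
                   aggregation = "character", classLabel = "character",
                   subjectScope = "character"))

setValidity("GAKCalibration", function(object) {
    if (object@sigmaOpt <= 0) return("sigmaOpt must be positive")
    if (length(object@stdRange) != 2L || diff(object@stdRange) < 0)
        return("stdRange must be an ordered pair")
    ar <- object@acceptanceRange
    if (length(ar) != 2L || ar[1] > ar[2] || ar[1] < 0 || ar[2] > 1)
        return("acceptanceRange must be an ordered pair within [0,1]")
    TRUE
})

#' MonitorConfig: settings for the training and denoising monitors
#'
#' Defaults mirror the study protocol: check every 50th epoch up to 4500,
#' score a batch of 128 synthetic sequences, require two consecutive
#' checkpoints (100 epochs) for a decision, 25\% of scores in range for the
#' calibrated-GAK rule; denoising runs 3000 steps monitored every 30th.
#'
#' @slot epochInterval epochs between training checkpoints.
#' @slot maxEpochs training horizon.
#' @slot syntheticBatch synthetic sequences scored per checkpoint.
#' @slot patienceChecks consecutive checkpoints needed for a stop decision.
#' @slot inRangeFraction minimal fraction of scores inside the acceptance
#'   range (calibrated-GAK rule).
#' @slot denoiseSteps denoising horizon.
#' @slot denoiseInterval steps between denoising checkpoints.
#' @slot metric \code{"copt_gak"}, \code{"cosine_psd"} or \code{"cosine_time"}.
#' @slot calibration a \linkS4class{GAKCalibration} (required for
#'   \code{"copt_gak"}) or NULL.
#' @slot welch \linkS4class{WelchConfig} used for PSD-domain metrics.
#' @slot rangeMode \code{"two_sided"} (default) or \code{"one_sided"}
#'   acceptance range.
#' @export
setClass("MonitorConfig",
    representation(epochInterval = "integer", maxEpochs = "integer",
                   syntheticBatch = "integer", patienceChecks = "integer",
                   inRangeFraction = "numeric", denoiseSteps = "integer",
                   denoiseInterval = "integer", metric = "character",
                   calibration = "ANY", welch = "WelchConfig",
                   rangeMode = "character"))

setValidity("MonitorConfig", function(object) {
    if (!object@metric %in% c("copt_gak", "cosine_psd", "cosine_time"))
        return("metric must be copt_gak/cosine_psd/cosine_time")
    if (object@metric == "copt_gak" && !is(object@calibration, "GAKCalibration"))
        return("metric 'copt_gak' requires a GAKCalibration")
    if (object@epochInterval < 1L || object@denoiseInterval < 1L)
        return("intervals must be >= 1")
    if (object@inRangeFraction < 0 || object@inRangeFraction > 1)
        return("inRangeFraction must be in [0,1]")
    if (!object@rangeMode %in% c("two_sided", "one_sided"))
        return("rangeMode must be two_sided or one_sided")
    TRUE
})

#' @rdname MonitorConfig-class
#' @param epochInterval,maxEpochs,syntheticBatch,patienceChecks see slots.
#' @param inRangeFraction,denoiseSteps,denoiseInterval,metric see slots.
#' @param calibration,welch,rangeMode see slots.
#' @return A \linkS4class{MonitorConfig}.
#' @export
MonitorConfig <- function(metric = c("copt_gak", "cosine_psd", "cosine_time"),
                          calibration = NULL,
                          epochInterval = 50L, maxEpochs = 4500L,
                          syntheticBatch = 128L, patienceChecks = 2L,
                          inRangeFraction = 0.25,
                          denoiseSteps = 3000L, denoiseInterval = 30L,
                          welch = WelchConfig(), rangeMode = "two_sided") {
    metric <- match.arg(metric)
    new("MonitorConfig", epochInterval = as.integer(epochInterval),
        maxEpochs = as.integer(maxEpochs),
        syntheticBatch = as.integer(syntheticBatch),
        patienceChecks = as.integer(patienceChecks),
        inRangeFraction = inRangeFraction,
        denoiseSteps = as.integer(denoiseSteps),
        denoiseInterval = as.integer(denoiseInterval),
        metric = metric, calibration = calibration, welch = welch,
        rangeMode = rangeMode)
}

#' MonitorTrace: the record of a monitored run
#'
#' @slot checkpoints data.frame with columns step, mean, sd,
#'   in_range_fraction (NA for cosine metrics).
#' @slot scores list of per-sequence score vectors, one per checkpoint.
#' @slot stopStep step/epoch at which the rule fired, or NA.
#' @slot bestStep checkpoint with the maximal mean score at or before the
#'   stop.
#' @slot stopReason one of \code{"in_range_rule"},
#'   \code{"local_max_patience"}, \code{"two_consecutive_drops"},
#'   \code{"horizon_reached"}.
#' @slot seed RNG seed recorded for the checkpoint batches.
#' @export
setClass("MonitorTrace",
    representation(checkpoints = "data.frame", scores = "list",
                   stopStep = "integer", bestStep = "integer",
                   stopReason = "character", seed = "integer"))

setValidity("MonitorTrace", function(object) {
    st <- object@checkpoints$step
    if (length(st) && is.unsorted(st, strictly = TRUE))
        return("checkpoint steps must be strictly increasing")
    if (!object@stopReason %in% c("in_range_rule", "local_max_patience",
                                  "two_consecutive_drops", "horizon_reached",
                                  "aborted"))
        return("unknown stopReason")
    TRUE
})

#' SchedulerConfig: per-channel linear diffusion-rate schedule
#'
#' Linear beta schedule for the forward noising process, with independent
#' start/end rates per sensor channel (e.g. a distinct rate for a rope
#' velocity channel than for accelerometer axes).
#'
#' @slot steps number of diffusion steps.
#' @slot betaStart,betaEnd per-channel schedule endpoints, recycled to the
#'   channel count at use time; each in (0, 1) with betaStart <= betaEnd.
#' @export
setClass("SchedulerConfig",
    representation(steps = "integer", betaStart = "numeric",
                   betaEnd = "numeric"))

setValidity("SchedulerConfig", function(object) {
    if (object@steps < 1L) return("steps must be >= 1")
    if (length(object@betaStart) != length(object@betaEnd))
        return("betaStart and betaEnd must have equal length")
    if (any(object@betaStart <= 0) || any(object@betaEnd >= 1) ||
        any(object@betaStart > object@betaEnd))
        return("each channel needs 0 < betaStart <= betaEnd < 1")
    TRUE
})

#' @rdname SchedulerConfig-class
#' @param steps,betaStart,betaEnd see slots.
#' @return A \linkS4class{SchedulerConfig}.
#' @export
SchedulerConfig <- function(steps = 3000L, betaStart = 1e-4, betaEnd = 2e-2) {
    new("SchedulerConfig", steps = as.integer(steps),
        betaStart = betaStart, betaEnd = betaEnd)
}

#' SynthSpec: recipe for seeded IMU-like synthetic datasets
#'
#' Describes cyclic activity classes as multi-harmonic waveforms (label,
#' fundamental frequency, harmonic amplitudes, additive noise sd) with
#' multiplicative per-subject jitter of frequency and amplitude — the
#' structure (within-class similarity, between-subject variation) that the
#' class-optimized bandwidth calibration assumes.
#'
#' @slot nSubjects number of subjects.
#' @slot classes list of class descriptors: list(label, fundamental_hz,
#'   harmonic_amplitudes, noise_sd).
#' @slot sampleRate Hz (default 50).
#' @slot window window width in timesteps (default 160).
#' @slot nChannels number of channels (default 6: AX,AY,AZ,GX,GY,GZ).
#' @slot perSubjectJitter fractional spread of frequency/amplitude.
#' @slot windowsPerSubject windows generated per subject and class.
#' @slot seed RNG seed; fully determines the output.
#' @export
setClass("SynthSpec",
    representation(nSubjects = "integer", classes = "list",
                   sampleRate = "numeric", window = "integer",
                   nChannels = "integer", perSubjectJitter = "numeric",
                   windowsPerSubject = "integer", seed = "integer"))

setValidity("SynthSpec", function(object) {
    nyq <- object@sampleRate / 2
    for (cl in object@classes) {
        if (is.null(cl$label)) return("every class needs a label")
        if (!is.null(cl$fundamental_hz) && cl$fundamental_hz >= nyq)
            return(sprintf("class '%s': fundamental >= Nyquist", cl$label))
        if (!is.null(cl$envelope_width_s) && cl$envelope_width_s <= 0)
            return(sprintf("class '%s': envelope width must be > 0",
                           cl$label))
        if (!is.null(cl$noise_sd) && cl$noise_sd < 0)
            return("noise_sd must be >= 0")
    }
    if (object@perSubjectJitter < 0) return("perSubjectJitter must be >= 0")
    if (object@nSubjects < 1L || object@windowsPerSubject < 2L)
        return("need >= 1 subject and >= 2 windows per subject")
    TRUE
})

#' @rdname SynthSpec-class
#' @param nSubjects,classes,sampleRate,window,nChannels see slots.
#' @param perSubjectJitter,windowsPerSubject,seed see slots.
#' @return A \linkS4class{SynthSpec}.
#' @export
SynthSpec <- function(nSubjects = 12L, classes = cyclicClassPresets(),
                      sampleRate = 50, window = 160L, nChannels = 6L,
                      perSubjectJitter = 0.08, windowsPerSubject = 4L,
                      seed = 7L) {
    new("SynthSpec", nSubjects = as.integer(nSubjects), classes = classes,
        sampleRate = as.numeric(sampleRate), window = as.integer(window),
        nChannels = as.integer(nChannels),
        perSubjectJitter = perSubjectJitter,
        windowsPerSubject = as.integer(windowsPerSubject),
        seed = as.integer(seed))
}

#' LinearDenoiser: minimal noise-prediction model for the demo diffusion
#' harness
#'
#' Predicts the injected noise as \eqn{\sqrt{1-\bar\alpha_t}} times a
#' learned timesteps x timesteps linear map of the noised signal, with one
#' weight matrix per coarse diffusion-time bin and channel (the
#' fast-varying noise scale is carried analytically; only the slowly
#' varying signal-covariance structure is learned).  Deliberately minimal:
#' enough capacity to learn second-order structure of quasi-periodic
#' signals, which is what the monitors need to observe improving sample
#' quality.
#'
#' @slot weights array T x T x nBins x channels.
#' @slot nChannels channel count the model was trained on (one weight set
#'   per channel).
#' @slot nBins number of diffusion-time bins.
#' @slot binOfT integer vector mapping each diffusion step (1-based index
#'   of t = 0..steps-1) to its bin; bins are equal-width in
#'   \eqn{\log(1-\bar\alpha_t)}, where the learned inverse-covariance
#'   factor varies slowly (uniform-in-t bins would lump together steps
#'   whose optimal weights differ by orders of magnitude near t = 0).
#' @slot seqLength window length T the model operates on.
#' @slot trainedEpochs training epochs performed so far.
#' @export
setClass("LinearDenoiser",
    representation(weights = "array", nChannels = "integer",
                   nBins = "integer", binOfT = "integer",
                   seqLength = "integer", trainedEpochs = "integer"))
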