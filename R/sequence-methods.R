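#' @describeIn SensorSequence-class channel x time value matrix.
#' @param x object.
#' @export
setMethod("seqValues", "SensorSequence", function(x) x@values)

#' @describeIn SensorSequence-class sampling rate in Hz.
#' @export
setMethod("sampleRate", "SensorSequence", function(x) x@sampleRate)

#' @describeIn SensorSequence-class channel identifiers.
#' @export
setMethod("channelNames", "SensorSequence", function(x) x@channelNames)

#' @describeIn SensorSequence-class class label.
#' @export
setMethod("classLabel", "SensorSequence", function(x) x@classLabel)

#' @describeIn SensorSequence-class subject identifier.
#' @export
setMethod("subjectId", "SensorSequence", function(x) x@subjectId)

#' @describeIn SensorSequence-class number of channels.
#' @export
setMethod("nChannels", "SensorSequence", function(x) nrow(x@values))

#' @describeIn SensorSequence-class window length in timesteps.
#' @export
setMethod("seqLength", "SensorSequence", function(x) ncol(x@values))

setMethod("show", "SensorSequence", function(object) {
    cat(sprintf("SensorSequence: %d channel(s) x %d timesteps @ %g Hz [%s / %s]\n",
                nChannels(object), seqLength(object), object@sampleRate,
                object@classLabel, object@subjectId))
})

#' @describeIn SequenceSet-class list of member sequences.
#' @param x object.
#' @export
setMethod("sequences", "SequenceSet", function(x) x@sequences)

#' @describeIn SequenceSet-class pipeline role.
#' @export
setMethod("seqRole", "SequenceSet", function(x) x@role)

#' @describeIn SequenceSet-class number of member sequences.
#' @export
setMethod("nSequences", "SequenceSet", function(x) length(x@sequences))

#' @describeIn SequenceSet-class shared channel count.
#' @export
setMethod("nChannels", "SequenceSet", function(x) {
    if (nSequences(x) == 0L) 0L else nChannels(x@sequences[[1]])
})

#' @describeIn SequenceSet-class shared channel names.
#' @export
setMethod("channelNames", "SequenceSet", function(x) {
    if (nSequences(x) == 0L) character() else channelNames(x@sequences[[1]])
})

#' @describeIn SequenceSet-class shared sample rate.
#' @export
setMethod("sampleRate", "SequenceSet", function(x) {
    if (nSequences(x) == 0L) NA_real_ else sampleRate(x@sequences[[1]])
})

#' @describeIn SequenceSet-class subset by index, preserving order.
#' @param i indices.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "SequenceSet", function(x, i, j, ..., drop = FALSE) {
    initialize(x, sequences = x@sequences[i])
})

setMethod("show", "SequenceSet", function(object) {
    cat(sprintf("SequenceSet (role=%s): %d sequence(s)", object@role,
                nSequences(object)))
    if (nSequences(object) > 0L) {
        cat(sprintf(", %d channel(s) x %d timesteps @ %g Hz\n  classes: %s\n",
                    nChannels(object), seqLength(object@sequences[[1]]),
                    sampleRate(object),
                    paste(unique(classLabels(object)), collapse = ", ")))
    } else cat("\n")
})

#' Per-sequence labels of a set
#'
#' @param set a \linkS4class{SequenceSet}.
#' @return Character vector of per-sequence class labels / subject ids.
#' @export
classLabels <- function(set) {
    vapply(sequences(set), classLabel, character(1))
}

#' @rdname classLabels
#' @export
subjectIds <- function(set) {
    vapply(sequences(set), subjectId, character(1))
}

#' Filter a SequenceSet by class label
#'
#' @param set a \linkS4class{SequenceSet}.
#' @param class class label to keep.
#' @return The filtered \linkS4class{SequenceSet} (order preserved).
#' @export
filterClass <- function(set, class) {
    keep <- classLabels(set) == class
    if (!any(keep))
        stopf("class '%s' absent from %s set", class, seqRole(set),
              class = "coptgak_missing_class")
    set[which(keep)]
}

#' @describeIn PSDVector-class channels x bins power matrix.
#' @param x object.
#' @export
setMethod("psdPower", "PSDVector", function(x) x@power)

#' @describeIn PSDVector-class one-sided frequency grid in Hz.
#' @export
setMethod("psdFrequencies", "PSDVector", function(x) x@frequencies)

#' @describeIn PSDVector-class number of channels.
#' @export
setMethod("nChannels", "PSDVector", function(x) nrow(x@power))

setMethod("show", "PSDVector", function(object) {
    cat(sprintf("PSDVector: %d channel(s) x %d bins, 0..%g Hz (M=%d, overlap=%d, %s)\n",
                nrow(object@power), ncol(object@power),
                max(object@frequencies), object@config@subwindowLength,
                object@config@overlap, object@config@windowFunction))
})

#' @describeIn GAKCalibration-class optimized bandwidth.
#' @param x object.
#' @export
setMethod("sigmaOpt", "GAKCalibration", function(x) x@sigmaOpt)

#' @describeIn GAKCalibration-class monitor target score range.
#' @export
setMethod("acceptanceRange", "GAKCalibration", function(x) x@acceptanceRange)

#' @describeIn GAKCalibration-class full (sigma, mean, sd) sweep.
#' @export
setMethod("sweepCurve", "GAKCalibration", function(x) x@sweep)

setMethod("show", "GAKCalibration", function(object) {
    cat(sprintf(paste0(
        "GAKCalibration [%s / %s]\n",
        "  sigma_opt = %.6g  (aggregation: %s)\n",
        "  mean score = %.4f, sd = %.4f  (sd constraint [%.3g, %.3g])\n",
        "  acceptance range = [%.4f, %.4f]; sweep: %d grid points, %d feasible\n"),
        object@classLabel, object@subjectScope, object@sigmaOpt,
        object@aggregation, object@meanScore, object@stdScore,
        object@stdRange[1], object@stdRange[2],
        object@acceptanceRange[1], object@acceptanceRange[2],
        nrow(object@sweep), sum(object@sweep$feasible)))
})

#' @describeIn MonitorTrace-class per-checkpoint summary table.
#' @param x object.
#' @export
setMethod("checkpoints", "MonitorTrace", function(x) x@checkpoints)

#' @describeIn MonitorTrace-class step at which the rule fired (NA when the
#'   horizon was reached).
#' @export
setMethod("stopStep", "MonitorTrace", function(x) x@stopStep)

#' @describeIn MonitorTrace-class checkpoint with the best mean score.
#' @export
setMethod("bestStep", "MonitorTrace", function(x) x@bestStep)

#' @describeIn MonitorTrace-class which rule ended the run.
#' @export
setMethod("stopReason", "MonitorTrace", function(x) x@stopReason)

setMethod("show", "MonitorTrace", function(object) {
    cat(sprintf(paste0(
        "MonitorTrace: %d checkpoint(s)\n",
        "  stop at %s (%s); best checkpoint %s (mean score %.4f)\n"),
        nrow(object@checkpoints),
        ifelse(is.na(object@stopStep), "horizon", object@stopStep),
        object@stopReason, object@bestStep,
        if (nrow(object@checkpoints))
            object@checkpoints$mean[match(object@bestStep,
                                          object@checkpoints$step)]
        else NA_real_))
})

setMethod("show", "SynthSpec", function(object) {
    cat(sprintf("SynthSpec: %d subject(s) x %d class(es), %d x %d windows @ %g Hz, seed %d\n",
                object@nSubjects, length(object@classes), object@nChannels,
                object@window, object@sampleRate, object@seed))
})
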