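# Periodic taper windows; periodic Hann satisfies constant overlap-add at
# the hop sizes used here, which makes the STFT exactly invertible on
# interior samples.
taper_window <- function(n, kind = c("hann", "rect")) {
    kind <- match.arg(kind)
    if (kind == "rect") return(rep(1, n))
    0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)
}

#' Segment a long recording into fixed-width windows
#'
#' Windows start every \code{width - overlap} samples; a trailing remainder
#' shorter than \code{width} is dropped.  The defaults (width 160 at 50 Hz,
#' overlap 40) are the study's operating point for activity windows.
#'
#' @param recording a \linkS4class{SensorSequence}.
#' @param width window width in timesteps.
#' @param overlap samples shared by consecutive windows (0 <= overlap <
#'   width).
#' @param role role stamped on the output set.
#' @return A \linkS4class{SequenceSet} with
#'   \code{floor((L - width)/(width - overlap)) + 1} windows.
#' @examples
#' rec <- SensorSequence(matrix(rnorm(400), 1), sampleRate = 50)
#' nSequences(slidingWindow(rec, 160, 40))  # 3 windows at 0, 120, 240
#' @export
slidingWindow <- function(recording, width = 160L, overlap = 40L,
                          role = "train") {
    width <- as.integer(width); overlap <- as.integer(overlap)
    if (overlap < 0L || overlap >= width)
        stopf("need 0 <= overlap < width", class = "coptgak_config_error")
    L <- seqLength(recording)
    if (L < width)
        stopf("recording (%d samples) shorter than window width %d", L, width,
              class = "coptgak_empty_error")
    step <- width - overlap
    starts <- seq.int(1L, L - width + 1L, by = step)
    v <- seqValues(recording)
    wins <- lapply(starts, function(s)
        SensorSequence(v[, s:(s + width - 1L), drop = FALSE],
                       sampleRate = sampleRate(recording),
                       channelNames = channelNames(recording),
                       classLabel = classLabel(recording),
                       subjectId = subjectId(recording)))
    SequenceSet(wins, role = role)
}

# one-sided rfft of a real vector: bins 0..floor(n/2)
rfft <- function(x) {
    n <- length(x)
    stats::fft(x)[seq_len(n %/% 2L + 1L)]
}

# inverse of rfft for even/odd n
irfft <- function(X, n) {
    full <- complex(n)
    nb <- length(X)
    full[seq_len(nb)] <- X
    if (n %% 2L == 0L) {
        if (nb > 2L) full[n:(nb + 1L)] <- Conj(X[2L:(nb - 1L)])
    } else {
        full[n:(nb + 1L)] <- Conj(X[2L:nb])
    }
    Re(stats::fft(full, inverse = TRUE)) / n
}

#' Short-time Fourier transform of a window
#'
#' Per-channel complex frames with periodic-Hann tapering.  The defaults
#' (segment 22, overlap 20) match the time-frequency representation used by
#' the generative pipeline; \code{\link{istft}} inverts the transform.
#'
#' @param window a \linkS4class{SensorSequence}.
#' @param stftWindow segment length.
#' @param stftOverlap overlap between consecutive segments.
#' @param windowFunction \code{"hann"} or \code{"rect"}.
#' @return A \linkS4class{SpectralSequence}.
#' @export
stft <- function(window, stftWindow = 22L, stftOverlap = 20L,
                 windowFunction = "hann") {
    M <- as.integer(stftWindow); ov <- as.integer(stftOverlap)
    if (ov >= M || ov < 0L)
        stopf("need 0 <= stftOverlap < stftWindow", class = "coptgak_config_error")
    L <- seqLength(window)
    if (L < M)
        stopf("window length %d < stft segment %d", L, M,
              class = "coptgak_input_error")
    hop <- M - ov
    starts <- seq.int(1L, L - M + 1L, by = hop)
    w <- taper_window(M, windowFunction)
    nb <- M %/% 2L + 1L
    v <- seqValues(window)
    frames <- array(complex(1), dim = c(nrow(v), nb, length(starts)))
    for (ch in seq_len(nrow(v)))
        for (k in seq_along(starts)) {
            seg <- v[ch, starts[k]:(starts[k] + M - 1L)] * w
            frames[ch, , k] <- rfft(seg)
        }
    new("SpectralSequence", frames = frames, stftWindow = M,
        stftOverlap = ov, windowFunction = windowFunction,
        originalLength = L, sampleRate = sampleRate(window),
        channelNames = channelNames(window))
}

#' Inverse STFT (overlap-add with window-squared normalization)
#'
#' Reconstructs the time-domain window from \code{\link{stft}} frames;
#' exact to ~1e-8 on interior samples under the Hann/COLA configuration.
#' Needed because generation can happen in the frequency domain while
#' similarity scoring consumes time-domain signals.
#'
#' @param spec a \linkS4class{SpectralSequence}.
#' @param classLabel,subjectId labels for the reconstructed sequence.
#' @return A \linkS4class{SensorSequence} of the original length.
#' @export
istft <- function(spec, classLabel = "unknown", subjectId = "unknown") {
    stopifnot(is(spec, "SpectralSequence"))
    d <- dim(spec@frames)
    M <- spec@stftWindow
    if (d[2] != M %/% 2L + 1L)
        stopf("frame bin count %d inconsistent with stftWindow %d", d[2], M,
              class = "coptgak_validation_error")
    hop <- M - spec@stftOverlap
    L <- spec@originalLength
    starts <- seq.int(1L, L - M + 1L, by = hop)
    if (length(starts) != d[3])
        stopf("frame count %d inconsistent with geometry", d[3],
              class = "coptgak_validation_error")
    w <- taper_window(M, spec@windowFunction)
    out <- matrix(0, nrow = d[1], ncol = L)
    norm <- numeric(L)
    for (k in seq_along(starts)) {
        idx <- starts[k]:(starts[k] + M - 1L)
        norm[idx] <- norm[idx] + w^2
        for (ch in seq_len(d[1]))
            out[ch, idx] <- out[ch, idx] + irfft(spec@frames[ch, , k], M) * w
    }
    nz <- norm > .Machine$double.eps
    out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, norm[nz], "/")
    SensorSequence(out, sampleRate = spec@sampleRate,
                   channelNames = spec@channelNames,
                   classLabel = classLabel, subjectId = subjectId)
}

#' Fit and apply per-channel scaling
#'
#' \code{scaleChannels} fits per-channel scaling parameters on a set
#' (intended: the training set) and applies them; \code{applyChannelScaling}
#' reuses fitted parameters on another set.  \code{"standardize"} maps the
#' fitting set to mean 0 / sd 1 per channel, \code{"minmax_normalize"} maps
#' the fitting-set range to [0, 1].
#'
#' @param set a \linkS4class{SequenceSet}.
#' @param mode scaling mode, recycled across channels: per channel
#'   \code{"standardize"} or \code{"minmax_normalize"}.
#' @return \code{scaleChannels}: list with elements \code{set} (scaled) and
#'   \code{params} (per-channel data.frame).
#' @export
scaleChannels <- function(set, mode = "standardize") {
    nc <- nChannels(set)
    if (nSequences(set) == 0L)
        stopf("cannot fit scaling on an empty set", class = "coptgak_input_error")
    mode <- rep_len(mode, nc)
    stopifnot(all(mode %in% c("standardize", "minmax_normalize")))
    allv <- do.call(cbind, lapply(sequences(set), seqValues))  # nc x total
    params <- data.frame(channel = channelNames(set), mode = mode,
                         center = 0, scale = 1)
    for (ch in seq_len(nc)) {
        x <- allv[ch, ]
        if (mode[ch] == "standardize") {
            s <- stats::sd(x)
            if (s < .Machine$double.eps)
                stopf("channel '%s' has zero variance; cannot standardize",
                      channelNames(set)[ch], class = "coptgak_validation_error")
            params$center[ch] <- mean(x); params$scale[ch] <- s
        } else {
            r <- range(x)
            if (diff(r) < .Machine$double.eps)
                stopf("channel '%s' is constant; cannot minmax-normalize",
                      channelNames(set)[ch], class = "coptgak_validation_error")
            params$center[ch] <- r[1]; params$scale[ch] <- diff(r)
        }
    }
    list(set = applyChannelScaling(set, params), params = params)
}

#' @rdname scaleChannels
#' @param params fitted parameter table from \code{scaleChannels}.
#' @return \code{applyChannelScaling}: the scaled \linkS4class{SequenceSet}.
#' @export
applyChannelScaling <- function(set, params) {
    seqs <- lapply(sequences(set), function(s) {
        v <- (seqValues(s) - params$center) / params$scale
        SensorSequence(v, sampleRate = sampleRate(s),
                       channelNames = channelNames(s),
                       classLabel = classLabel(s), subjectId = subjectId(s))
    })
    initialize(set, sequences = seqs)
}
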