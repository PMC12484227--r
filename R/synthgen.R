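#' Built-in synthetic class recipes
#'
#' \code{cyclicClassPresets} describes four quasi-periodic activity
#' classes (multi-harmonic waveforms with distinct fundamentals, standing
#' in for walking / running / jumping / cycling styles of thigh-IMU data);
#' \code{acyclicClassPresets} describes transient-burst classes (falls,
#' rope pulls, stillstanding) with class-specific Gaussian envelope widths
#' and amplitudes.
#'
#' @return List of class descriptor lists.
#' @export
cyclicClassPresets <- function() {
    list(
        list(label = "Walking", fundamental_hz = 1.7,
             harmonic_amplitudes = c(1, 0.5, 0.2), noise_sd = 0.1),
        list(label = "Running", fundamental_hz = 2.8,
             harmonic_amplitudes = c(1, 0.3), noise_sd = 0.1),
        list(label = "JumpUp", fundamental_hz = 2.2,
             harmonic_amplitudes = c(1, 0.6, 0.3), noise_sd = 0.1),
        list(label = "Cycling", fundamental_hz = 1.0,
             harmonic_amplitudes = c(1, 0.2), noise_sd = 0.1))
}

#' @rdname cyclicClassPresets
#' @export
acyclicClassPresets <- function() {
    list(
        list(label = "Falling", envelope_width_s = 0.08, amplitude = 3,
             bursts_per_window = 1L, noise_sd = 0.1),
        list(label = "RopePull", envelope_width_s = 0.4, amplitude = 1.5,
             bursts_per_window = 2L, noise_sd = 0.1),
        list(label = "Stillstanding", envelope_width_s = 0.2, amplitude = 0,
             bursts_per_window = 1L, noise_sd = 0.1))
}

default_channel_names <- function(n) {
    base <- c("AX", "AY", "AZ", "GX", "GY", "GZ")
    if (n <= 6L) base[seq_len(n)] else c(base, paste0("ch", 7:n))[seq_len(n)]
}

# deterministic per-class, per-channel gain pattern so channels carry the
# same rhythm at different magnitudes (as IMU axes do)
channel_gain <- function(channel, class_idx) {
    0.4 + 0.6 / (1 + ((channel + class_idx) %% 3L))
}

#' Generate a seeded cyclic IMU-like dataset
#'
#' Each sequence is a per-channel sum of harmonics of a class fundamental
#' (with multiplicative per-subject jitter of frequency and amplitudes,
#' random phases, and additive white noise), generated as one continuous
#' recording per subject and class and segmented into non-overlapping
#' windows.  The final window of every subject/class recording forms the
#' validation set; the rest form the training set.  The seed fully
#' determines the output.
#'
#' @param spec a \linkS4class{SynthSpec}; classes must carry
#'   \code{fundamental_hz}, \code{harmonic_amplitudes}, \code{noise_sd}.
#' @return List with elements \code{train} and \code{validation}
#'   (\linkS4class{SequenceSet}s).
#' @examples
#' d <- makeCyclicDataset(SynthSpec(nSubjects = 2,
#'     classes = cyclicClassPresets()[1:2], seed = 1))
#' nSequences(d$train); nSequences(d$validation)
#' @export
makeCyclicDataset <- function(spec = SynthSpec()) {
    stopifnot(is(spec, "SynthSpec"))
    validObject(spec)
    fs <- spec@sampleRate
    L <- spec@windowsPerSubject * spec@window
    tt <- (seq_len(L) - 1L) / fs
    cn <- default_channel_names(spec@nChannels)
    train <- list(); val <- list()
    with_seed(spec@seed, {
        for (s in seq_len(spec@nSubjects)) {
            for (k in seq_along(spec@classes)) {
                cl <- spec@classes[[k]]
                f_subj <- cl$fundamental_hz *
                    max(0.5, 1 + spec@perSubjectJitter * stats::rnorm(1))
                amps <- cl$harmonic_amplitudes *
                    pmax(0.2, 1 + spec@perSubjectJitter *
                             stats::rnorm(length(cl$harmonic_amplitudes)))
                v <- matrix(0, spec@nChannels, L)
                for (ch in seq_len(spec@nChannels)) {
                    g <- channel_gain(ch, k)
                    phases <- stats::runif(length(amps), 0, 2 * pi)
                    for (h in seq_along(amps))
                        v[ch, ] <- v[ch, ] + g * amps[h] *
                            sin(2 * pi * h * f_subj * tt + phases[h])
                    v[ch, ] <- v[ch, ] + stats::rnorm(L, sd = cl$noise_sd)
                }
                rec <- SensorSequence(v, sampleRate = fs, channelNames = cn,
                                      classLabel = cl$label,
                                      subjectId = sprintf("S%02d", s))
                wins <- sequences(slidingWindow(rec, spec@window, 0L))
                nw <- length(wins)
                train <- c(train, wins[seq_len(nw - 1L)])
                val <- c(val, wins[nw])
            }
        }
    })
    list(train = SequenceSet(train, role = "train"),
         validation = SequenceSet(val, role = "validation"))
}

#' Generate a seeded acyclic (transient-burst) dataset
#'
#' Sequences contain class-specific Gaussian-envelope bursts at random
#' onsets (amplitude and envelope width per class, random sign per
#' channel) plus white noise; a zero-amplitude class yields pure noise.
#'
#' @param spec a \linkS4class{SynthSpec}; classes must carry
#'   \code{envelope_width_s}, \code{amplitude}, \code{bursts_per_window},
#'   \code{noise_sd}.
#' @return List with elements \code{train} and \code{validation}.
#' @export
makeAcyclicDataset <- function(spec = SynthSpec(classes = acyclicClassPresets())) {
    stopifnot(is(spec, "SynthSpec"))
    fs <- spec@sampleRate
    W <- spec@window
    tt <- (seq_len(W) - 1L) / fs
    cn <- default_channel_names(spec@nChannels)
    train <- list(); val <- list()
    with_seed(spec@seed, {
        for (s in seq_len(spec@nSubjects)) {
            for (k in seq_along(spec@classes)) {
                cl <- spec@classes[[k]]
                amp_subj <- cl$amplitude *
                    max(0, 1 + spec@perSubjectJitter * stats::rnorm(1))
                wins <- lapply(seq_len(spec@windowsPerSubject), function(w) {
                    v <- matrix(stats::rnorm(spec@nChannels * W,
                                             sd = cl$noise_sd),
                                spec@nChannels, W)
                    for (b in seq_len(cl$bursts_per_window)) {
                        t0 <- stats::runif(1, 0.15, 0.85) * W / fs
                        env <- amp_subj *
                            exp(-(tt - t0)^2 / (2 * cl$envelope_width_s^2))
                        sgn <- sample(c(-1, 1), spec@nChannels, replace = TRUE)
                        for (ch in seq_len(spec@nChannels))
                            v[ch, ] <- v[ch, ] +
                                sgn[ch] * channel_gain(ch, k) * env
                    }
                    SensorSequence(v, sampleRate = fs, channelNames = cn,
                                   classLabel = cl$label,
                                   subjectId = sprintf("S%02d", s))
                })
                nw <- length(wins)
                train <- c(train, wins[seq_len(nw - 1L)])
                val <- c(val, wins[nw])
            }
        }
    })
    list(train = SequenceSet(train, role = "train"),
         validation = SequenceSet(val, role = "validation"))
}

#' Generate a batch of i.i.d. standard-normal sequences
#'
#' The initial state of the reverse diffusion process, and the noise
#' baseline against which sample quality is judged.
#'
#' @param n number of sequences (>= 1).
#' @param nChannels,len channel count and window length.
#' @param sampleRate Hz.
#' @param seed RNG seed.
#' @param channelNames optional channel names.
#' @return A \linkS4class{SequenceSet} with role \code{"synthetic"}.
#' @export
makeNoiseBatch <- function(n, nChannels = 6L, len = 160L, sampleRate = 50,
                           seed = 1L, channelNames = NULL) {
    if (n < 1L) stopf("n must be >= 1", class = "coptgak_input_error")
    if (is.null(channelNames)) channelNames <- default_channel_names(nChannels)
    seqs <- with_seed(seed, lapply(seq_len(n), function(i)
        SensorSequence(matrix(stats::rnorm(nChannels * len), nChannels, len),
                       sampleRate = sampleRate, channelNames = channelNames,
                       classLabel = "noise", subjectId = "noise")))
    SequenceSet(seqs, role = "synthetic")
}
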