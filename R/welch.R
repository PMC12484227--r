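#' Welch power spectral density of a window
#'
#' Averaged-periodogram PSD estimate, the representation on which the
#' headline similarity scores are computed: the signal is split into K
#' overlapping subsequences, each tapered by the configured window
#' function, the per-subsequence periodogram \eqn{P = |DFT|^2 / M} is
#' formed, and the K periodograms are averaged.  The spectrum is one-sided
#' (bins 0..floor(M/2)) with interior bins folded so that total one-sided
#' power equals the full-spectrum power.  Discarding phase this way removes
#' the temporal position of the waveform within the window, which is what
#' makes the PSD a robust comparison domain for quasi-periodic activity
#' signals.
#'
#' @param window a \linkS4class{SensorSequence} (length >= M).
#' @param config a \linkS4class{WelchConfig}; default M = 64, overlap 32,
#'   periodic Hann (>= 3 averaged periodograms for a 160-sample window).
#' @return A \linkS4class{PSDVector}.
#' @examples
#' s <- SensorSequence(matrix(sin(2 * pi * 5 * (0:159) / 50), 1), 50)
#' p <- welchPSD(s)
#' psdFrequencies(p)[which.max(psdPower(p)[1, ])]  # ~5 Hz
#' @export
welchPSD <- function(window, config = WelchConfig()) {
    stopifnot(is(window, "SensorSequence"), is(config, "WelchConfig"))
    M <- config@subwindowLength
    L <- seqLength(window)
    if (L < M)
        stopf("sequence length %d < Welch subwindow %d", L, M,
              class = "coptgak_input_error")
    hop <- M - config@overlap
    starts <- seq.int(1L, L - M + 1L, by = hop)
    w <- taper_window(M, config@windowFunction)
    nb <- M %/% 2L + 1L
    v <- seqValues(window)
    pow <- matrix(0, nrow = nrow(v), ncol = nb)
    for (ch in seq_len(nrow(v))) {
        acc <- numeric(nb)
        for (s in starts) {
            seg <- v[ch, s:(s + M - 1L)] * w
            sp <- abs(stats::fft(seg))^2 / M          # full periodogram, Eq form
            one <- sp[seq_len(nb)]
            if (M %% 2L == 0L) {
                if (nb > 2L) one[2L:(nb - 1L)] <- 2 * one[2L:(nb - 1L)]
            } else if (nb > 1L) one[2L:nb] <- 2 * one[2L:nb]
            acc <- acc + one
        }
        pow[ch, ] <- acc / length(starts)
    }
    rownames(pow) <- channelNames(window)
    freqs <- (seq_len(nb) - 1L) * sampleRate(window) / M
    new("PSDVector", power = pow, frequencies = freqs, config = config)
}

#' Welch PSDs for every sequence of a set
#'
#' @param set a \linkS4class{SequenceSet}.
#' @param config a \linkS4class{WelchConfig}.
#' @return List of \linkS4class{PSDVector}, one per sequence, in order.
#' @export
welchPSDSet <- function(set, config = WelchConfig()) {
    lapply(sequences(set), welchPSD, config = config)
}

# channels-keyed list of bins x n matrices for fast kernel sweeps
psd_channel_matrices <- function(set, config) {
    psds <- welchPSDSet(set, config)
    nc <- nChannels(set)
    lapply(seq_len(nc), function(ch)
        vapply(psds, function(p) p@power[ch, ], numeric(ncol(psds[[1]]@power))))
}

time_channel_matrices <- function(set) {
    nc <- nChannels(set)
    n <- seqLength(sequences(set)[[1]])
    lapply(seq_len(nc), function(ch)
        vapply(sequences(set), function(s) seqValues(s)[ch, ], numeric(n)))
}

# dispatch on domain; returns list over channels of (length x nseq) matrices
domain_matrices <- function(set, domain, config) {
    if (domain == "psd") psd_channel_matrices(set, config)
    else time_channel_matrices(set)
}
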