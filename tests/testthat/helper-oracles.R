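options(coptgak.log_level = "warn")

# local alignment kernel, same convention as the implementation
gak_local_kernel <- function(a, b, sigma) {
    d <- -(a - b)^2 / (2 * sigma^2)
    exp(d) / (2 - exp(d))
}

# independent oracle: exhaustive enumeration of all monotone alignment
# paths (steps right/down/diagonal); the value is the sum over paths of
# the product of local kernels at every visited cell.  Path log-weights
# are accumulated and combined with log-sum-exp so the oracle reaches the
# same small-bandwidth regimes as the log-space DP.
gak_bruteforce_log <- function(x, y, sigma) {
    n <- length(x); m <- length(y)
    log_kappa <- function(a, b) {
        d <- -(a - b)^2 / (2 * sigma^2)
        d - log(2 - exp(d))
    }
    logs <- numeric(0)
    rec <- function(i, j, acc) {
        acc <- acc + log_kappa(x[i], y[j])
        if (i == n && j == m) {
            logs[length(logs) + 1L] <<- acc
            return(invisible(NULL))
        }
        if (i < n) rec(i + 1, j, acc)
        if (j < m) rec(i, j + 1, acc)
        if (i < n && j < m) rec(i + 1, j + 1, acc)
        invisible(NULL)
    }
    rec(1, 1, 0)
    mx <- max(logs)
    mx + log(sum(exp(logs - mx)))
}

gak_bruteforce <- function(x, y, sigma) exp(gak_bruteforce_log(x, y, sigma))

# direct-DFT periodogram of a tapered segment, one-sided fold, 1/M scale
periodogram_direct <- function(seg, taper) {
    M <- length(seg)
    xw <- seg * taper
    nb <- M %/% 2 + 1
    out <- numeric(nb)
    for (k in seq_len(M)) {
        s <- sum(xw * exp(-2i * pi * (k - 1) * (seq_len(M) - 1) / M))
        p <- Mod(s)^2 / M
        if (k <= nb) out[k] <- out[k] + p
        else out[M - k + 2] <- out[M - k + 2] + p
    }
    out
}

hann_periodic <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

# small multichannel sequence set with prescribed geometry
random_set <- function(n = 3, nch = 2, len = 32, seed = 1, role = "train",
                       labels = "A", subjects = "S1") {
    coptgak:::with_seed(seed, {
        seqs <- lapply(seq_len(n), function(i)
            SensorSequence(matrix(rnorm(nch * len), nch), sampleRate = 50,
                           classLabel = rep_len(labels, n)[i],
                           subjectId = rep_len(subjects, n)[i]))
        SequenceSet(seqs, role = role)
    })
}

# tiny quasi-periodic two-class dataset for fast calibration checks
small_cyclic <- function(seed = 11, classes = cyclicClassPresets()[1],
                         subjects = 4, window = 64L, nch = 2L) {
    makeCyclicDataset(SynthSpec(nSubjects = subjects, classes = classes,
                                window = window, nChannels = nch,
                                windowsPerSubject = 4L, seed = seed))
}
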