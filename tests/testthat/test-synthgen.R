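test_that("generation is fully determined by the seed", {
    s1 <- makeCyclicDataset(SynthSpec(nSubjects = 2,
                                      classes = cyclicClassPresets()[1:2],
                                      seed = 5))
    s2 <- makeCyclicDataset(SynthSpec(nSubjects = 2,
                                      classes = cyclicClassPresets()[1:2],
                                      seed = 5))
    s3 <- makeCyclicDataset(SynthSpec(nSubjects = 2,
                                      classes = cyclicClassPresets()[1:2],
                                      seed = 6))
    expect_identical(seqValues(sequences(s1$train)[[1]]),
                     seqValues(sequences(s2$train)[[1]]))
    expect_false(identical(seqValues(sequences(s1$train)[[1]]),
                           seqValues(sequences(s3$train)[[1]])))
    a1 <- makeAcyclicDataset(SynthSpec(nSubjects = 2,
                                       classes = acyclicClassPresets(),
                                       seed = 5))
    a2 <- makeAcyclicDataset(SynthSpec(nSubjects = 2,
                                       classes = acyclicClassPresets(),
                                       seed = 5))
    expect_identical(seqValues(sequences(a1$train)[[3]]),
                     seqValues(sequences(a2$train)[[3]]))
})

test_that("set sizes, labels and split structure are as configured", {
    spec <- SynthSpec(nSubjects = 3, classes = cyclicClassPresets()[1:2],
                      windowsPerSubject = 4L, seed = 2)
    d <- makeCyclicDataset(spec)
    expect_equal(nSequences(d$train), 3 * 2 * 3)   # all but last window
    expect_equal(nSequences(d$validation), 3 * 2)
    expect_setequal(unique(classLabels(d$train)), c("Walking", "Running"))
    expect_equal(seqRole(d$validation), "validation")
    expect_equal(channelNames(d$train),
                 c("AX", "AY", "AZ", "GX", "GY", "GZ"))
    expect_equal(seqLength(sequences(d$train)[[1]]), 160L)
})

test_that("a noiseless single harmonic peaks at its fundamental in every window", {
    spec <- SynthSpec(nSubjects = 2,
                      classes = list(list(label = "pure",
                                          fundamental_hz = 3.125,
                                          harmonic_amplitudes = 1,
                                          noise_sd = 0)),
                      perSubjectJitter = 0, nChannels = 2L, seed = 3)
    d <- makeCyclicDataset(spec)
    for (s in sequences(d$train)) {
        p <- welchPSD(s)                       # M = 64 -> 0.78125 Hz bins
        for (ch in 1:2)
            expect_equal(psdFrequencies(p)[which.max(psdPower(p)[ch, ])],
                         3.125)
    }
})

test_that("fundamentals above Nyquist are rejected", {
    expect_error(validObject(
        SynthSpec(classes = list(list(label = "x", fundamental_hz = 30,
                                      harmonic_amplitudes = 1,
                                      noise_sd = 0.1)))),
        "Nyquist")
})

test_that("within-class PSD similarity exceeds cross-class similarity", {
    spec <- SynthSpec(nSubjects = 4,
                      classes = list(
                          list(label = "slow", fundamental_hz = 1,
                               harmonic_amplitudes = 1, noise_sd = 0.1),
                          list(label = "fast", fundamental_hz = 3,
                               harmonic_amplitudes = 1, noise_sd = 0.1)),
                      nChannels = 2L, seed = 9)
    d <- makeCyclicDataset(spec)
    slow <- filterClass(d$train, "slow"); fast <- filterClass(d$train, "fast")
    within <- pairwiseScoreMatrix(slow, slow, "cosine", "psd")$scores
    cross <- pairwiseScoreMatrix(slow, fast, "cosine", "psd")$scores
    expect_gt(length(cross), 50)
    expect_gt(mean(within[upper.tri(within)]), mean(cross))
})

test_that("acyclic burst widths shape the PSD band balance", {
    mk <- function(width) SynthSpec(
        nSubjects = 3,
        classes = list(list(label = "b", envelope_width_s = width,
                            amplitude = 3, bursts_per_window = 1L,
                            noise_sd = 0.05)),
        nChannels = 1L, seed = 4)
    narrow <- makeAcyclicDataset(mk(0.05))
    wide <- makeAcyclicDataset(mk(0.5))
    lowfrac <- function(d) {
        mean(vapply(sequences(d$train), function(s) {
            p <- welchPSD(s)
            f <- psdFrequencies(p)
            sum(psdPower(p)[1, f <= 1.6]) / sum(psdPower(p)[1, ])
        }, numeric(1)))
    }
    expect_gt(lowfrac(wide), lowfrac(narrow))
})

test_that("a zero-amplitude burst class is pure noise", {
    spec <- SynthSpec(nSubjects = 2,
                      classes = list(list(label = "still",
                                          envelope_width_s = 0.2,
                                          amplitude = 0,
                                          bursts_per_window = 1L,
                                          noise_sd = 0.1)),
                      nChannels = 1L, seed = 8)
    d <- makeAcyclicDataset(spec)
    v <- do.call(c, lapply(sequences(d$train), function(s) as.numeric(seqValues(s))))
    expect_lt(abs(sd(v) - 0.1), 0.01)
    expect_lt(max(abs(v)), 0.1 * 6)
})

test_that("noise batches honor geometry and the central limit bound", {
    nb <- makeNoiseBatch(8L, nChannels = 3L, len = 100L, sampleRate = 50,
                         seed = 12)
    expect_equal(nSequences(nb), 8L)
    expect_equal(nChannels(nb), 3L)
    expect_equal(seqLength(sequences(nb)[[1]]), 100L)
    expect_equal(seqRole(nb), "synthetic")
    v <- do.call(c, lapply(sequences(nb), function(s) as.numeric(seqValues(s))))
    n <- length(v)
    expect_lt(abs(mean(v)), 3 / sqrt(n))
    expect_lt(abs(sd(v) - 1), 3 / sqrt(n))
    nb2 <- makeNoiseBatch(8L, nChannels = 3L, len = 100L, sampleRate = 50,
                          seed = 12)
    expect_identical(seqValues(sequences(nb)[[5]]),
                     seqValues(sequences(nb2)[[5]]))
    expect_error(makeNoiseBatch(0L), class = "coptgak_input_error")
})

test_that("the calibration pipeline finds a feasible bandwidth on a preset fixture", {
    d <- small_cyclic()        # 4 subjects, one cyclic class
    cal <- optimizeSigma(d$train, d$validation, welch = WelchConfig(32L, 16L))
    expect_gte(cal@stdScore, 0.09)
    expect_lte(cal@stdScore, 0.12)
})
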