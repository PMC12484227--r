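wc16 <- WelchConfig(16L, 8L)

test_that("a single train/validation pair has zero score spread everywhere", {
    tr <- random_set(n = 1, len = 24, seed = 1)
    va <- random_set(n = 1, len = 24, seed = 2, role = "validation")
    sw <- sigmaSweep(tr, va, sigmaGrid = c(0.1, 1, 10), welch = wc16)
    expect_equal(sw$sd, c(0, 0, 0))
})

test_that("sweep statistics are deterministic and monotone-calibrated", {
    d <- small_cyclic()
    tr <- d$train[1:6]; va <- d$validation[1:3]
    grid <- c(0.01, 0.01, 1, 10)           # duplicate grid point
    sw <- sigmaSweep(tr, va, grid, welch = WelchConfig(32L, 16L))
    expect_equal(sw$mean[1], sw$mean[2])
    expect_equal(sw$sd[1], sw$sd[2])
    # generous bandwidth scores above the high-selectivity regime
    expect_gt(sw$mean[4], sw$mean[1])
    expect_error(sigmaSweep(tr, va, numeric(0)),
                 class = "coptgak_config_error")
    expect_error(sigmaSweep(tr, va, c(-1, 1)),
                 class = "coptgak_config_error")
})

test_that("a vacuous constraint returns the global score maximum", {
    d <- small_cyclic()
    cal <- optimizeSigma(d$train[1:8], d$validation[1:4],
                         sigmaGrid = sigmaGridDefault(20),
                         stdRange = c(0, 1), welch = WelchConfig(32L, 16L))
    sw <- sweepCurve(cal)
    expect_true(all(sw$feasible))
    expect_equal(cal@meanScore, max(sw$mean))
    expect_equal(sigmaOpt(cal), sw$sigma[which.max(sw$mean)])
})

test_that("an unsatisfiable constraint raises NoFeasibleSigma carrying the sweep", {
    d <- small_cyclic()
    err <- tryCatch(
        optimizeSigma(d$train[1:8], d$validation[1:4],
                      sigmaGrid = sigmaGridDefault(15),
                      stdRange = c(0.98, 0.99), welch = WelchConfig(32L, 16L)),
        condition = identity)
    expect_s3_class(err, "coptgak_no_feasible_sigma")
    expect_true(is.data.frame(err$sweep))
    expect_equal(nrow(err$sweep), 15L)
})

test_that("the returned optimum is grid-feasible and grid-optimal", {
    d <- small_cyclic()
    cal <- optimizeSigma(d$train, d$validation, welch = WelchConfig(32L, 16L))
    sw <- sweepCurve(cal)
    feas <- sw[sw$feasible, ]
    expect_true(all(feas$sd >= cal@stdRange[1] & feas$sd <= cal@stdRange[2]))
    expect_true(cal@meanScore >= max(feas$mean) - 1e-15)
    expect_true(sigmaOpt(cal) %in% feas$sigma)
    expect_equal(cal@acceptanceRange,
                 c(max(0, cal@meanScore - cal@stdScore),
                   min(1, cal@meanScore + cal@stdScore)))
    # determinism
    cal2 <- optimizeSigma(d$train, d$validation, welch = WelchConfig(32L, 16L))
    expect_identical(sigmaOpt(cal2), sigmaOpt(cal))
    expect_identical(sweepCurve(cal2)$mean, sw$mean)
})

test_that("grid refinement around the optimum moves it by at most one step", {
    d <- small_cyclic(seed = 1)
    base <- sigmaGridDefault(30)
    cal <- optimizeSigma(d$train, d$validation, sigmaGrid = base,
                         welch = WelchConfig(32L, 16L))
    i <- match(sigmaOpt(cal), base)
    lo <- base[max(1, i - 1)]; hi <- base[min(length(base), i + 1)]
    fine <- sort(unique(c(base, exp(seq(log(lo), log(hi), length.out = 9)))))
    cal2 <- optimizeSigma(d$train, d$validation, sigmaGrid = fine,
                          welch = WelchConfig(32L, 16L))
    step <- log(base[2]) - log(base[1])
    expect_lt(abs(log(sigmaOpt(cal2)) - log(sigmaOpt(cal))), step + 1e-12)
})

test_that("per-class calibration is independent and errors name missing classes", {
    d <- small_cyclic(classes = cyclicClassPresets()[c(1, 4)])  # 1.7 vs 1.0 Hz
    cals <- calibratePerClass(d$train, d$validation,
                              welch = WelchConfig(32L, 16L))
    expect_named(cals, c("Walking", "Cycling"))
    single <- optimizeSigma(filterClass(d$train, "Walking"),
                            filterClass(d$validation, "Walking"),
                            welch = WelchConfig(32L, 16L),
                            classLabel = "Walking")
    expect_equal(sigmaOpt(cals$Walking), sigmaOpt(single))
    err <- tryCatch(calibratePerClass(d$train, d$validation,
                                      classes = c("Walking", "Yoga"),
                                      welch = WelchConfig(32L, 16L)),
                    condition = identity)
    expect_s3_class(err, "coptgak_missing_class")
    expect_match(conditionMessage(err), "Yoga")
})

test_that("two classes with identical data yield identical calibrations", {
    base <- random_set(n = 6, nch = 1, len = 32, seed = 5)
    relabel <- function(set, lab, role) {
        seqs <- lapply(sequences(set), function(s)
            SensorSequence(seqValues(s), sampleRate(s), channelNames(s),
                           classLabel = lab, subjectId = subjectId(s)))
        SequenceSet(seqs, role)
    }
    tr <- SequenceSet(c(sequences(relabel(base, "A", "train")),
                        sequences(relabel(base, "B", "train"))), "train")
    vb <- random_set(n = 3, nch = 1, len = 32, seed = 6, role = "validation")
    va <- SequenceSet(c(sequences(relabel(vb, "A", "validation")),
                        sequences(relabel(vb, "B", "validation"))),
                      "validation")
    cals <- calibratePerClass(tr, va, stdRange = c(0, 1), welch = wc16)
    expect_equal(sigmaOpt(cals$A), sigmaOpt(cals$B))
    expect_equal(cals$A@meanScore, cals$B@meanScore)
})

test_that("tighter sd constraints pick larger bandwidths and score a fixed pair higher", {
    d <- makeCyclicDataset(SynthSpec(nSubjects = 8,
                                     classes = cyclicClassPresets()[1],
                                     seed = 7))
    wc <- WelchConfig()
    grid <- sigmaGridDefault(30)
    cal1 <- optimizeSigma(d$train, d$validation, sigmaGrid = grid,
                          stdRange = stdRangePreset("sd1"), welch = wc)
    cal3 <- optimizeSigma(d$train, d$validation, sigmaGrid = grid,
                          stdRange = stdRangePreset("sd3"), welch = wc)
    expect_gt(sigmaOpt(cal1), sigmaOpt(cal3))
    # one fixed similar pair: a training window and the following window of
    # the same subject's recording
    x <- sequences(d$train)[[1]]; y <- sequences(d$train)[[2]]
    s1 <- multichannelScore(x, y, "gak", "psd", sigma = sigmaOpt(cal1),
                            welch = wc)$averaged
    s3 <- multichannelScore(x, y, "gak", "psd", sigma = sigmaOpt(cal3),
                            welch = wc)$averaged
    expect_gt(s1, s3)
})
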