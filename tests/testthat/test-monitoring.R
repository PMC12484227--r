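# sequences with a prescribed cosine against the fixed unit direction
unit_real <- function(len = 8) {
    SequenceSet(list(SensorSequence(matrix(c(1, rep(0, len - 1)), 1), 50)),
                "train")
}
cos_sequence <- function(co, len = 8) {
    v <- co * c(1, rep(0, len - 1)) +
        sqrt(1 - co^2) * c(0, 1, rep(0, len - 2))
    SensorSequence(matrix(v, 1), 50)
}
cos_batch <- function(co, len = 8) {
    SequenceSet(list(cos_sequence(co, len)), "synthetic")
}

fake_calibration <- function(range = c(0.4, 1)) {
    new("GAKCalibration", sigmaOpt = 1, meanScore = mean(range),
        stdScore = diff(range) / 2, stdRange = c(0.09, 0.12),
        acceptanceRange = range,
        sweep = data.frame(sigma = 1, mean = mean(range),
                           sd = diff(range) / 2, feasible = TRUE),
        aggregation = "best_match", classLabel = "A", subjectScope = "all")
}

test_that("batch scoring gives unit scores for a copy of the real set", {
    real <- random_set(n = 4, nch = 2, len = 32, seed = 1)
    mc <- MonitorConfig("copt_gak", fake_calibration(),
                        welch = WelchConfig(16L, 8L))
    sb <- scoreBatch(real, real, mc)
    expect_equal(sb$scores, rep(1, 4))
    expect_equal(sb$in_range_fraction, 1)
    bad <- random_set(n = 2, nch = 3, len = 32, seed = 2, role = "synthetic")
    expect_error(scoreBatch(real, bad, mc),
                 class = "coptgak_validation_error")
})

test_that("in-range counting is a plain fraction with inclusive bounds", {
    expect_equal(inRangeFraction(c(0.1, 0.5, 0.9), c(0.4, 1.0)), 2 / 3)
    expect_equal(inRangeFraction(c(0.4, 1.0), c(0.4, 1.0)), 1)
    expect_equal(inRangeFraction(c(0.39), c(0.4, 1.0)), 0)
})

test_that("the cosine patience rule reproduces the hand-simulated trace", {
    steps <- seq(50, 250, 50)
    means <- c(0.2, 0.4, 0.6, 0.5, 0.45)
    dec <- applyTrainingRule(steps, means, metric = "cosine_psd",
                             patience = 2L)
    expect_equal(dec$stop_index, 5L)          # epoch 250
    expect_equal(dec$reason, "local_max_patience")
    # never-stopping variants
    expect_true(is.na(applyTrainingRule(steps, c(1, 2, 3, 4, 5) / 5,
                                        metric = "cosine_time")$stop_index))
})

test_that("the in-range rule needs the threshold met at two consecutive checkpoints", {
    steps <- seq(50, 250, 50)
    fr <- c(0, 0.3, 0.3, 0, 0)
    dec <- applyTrainingRule(steps, rep(0.5, 5), fractions = fr,
                             metric = "copt_gak", minFraction = 0.25)
    expect_equal(dec$stop_index, 3L)          # epoch 150
    expect_equal(dec$reason, "in_range_rule")
    # isolated hits never fire
    dec2 <- applyTrainingRule(steps, rep(0.5, 5),
                              fractions = c(0.3, 0, 0.3, 0, 0.3),
                              metric = "copt_gak")
    expect_true(is.na(dec2$stop_index))
})

test_that("the denoising rule fires on two consecutive strict drops only", {
    steps <- seq(30, 150, 30)
    dec <- applyDenoisingRule(steps, c(0.1, 0.3, 0.5, 0.45, 0.4))
    expect_equal(dec$stop_index, 5L)          # step 150
    expect_equal(dec$reason, "two_consecutive_drops")
    expect_true(is.na(applyDenoisingRule(steps, rep(0.4, 5))$stop_index))
    expect_true(is.na(applyDenoisingRule(steps,
                                         c(0.1, 0.2, 0.3, 0.4, 0.5))$stop_index))
    # replay determinism
    dec2 <- applyDenoisingRule(steps, c(0.1, 0.3, 0.5, 0.45, 0.4))
    expect_identical(dec, dec2)
})

test_that("the training monitor walks the scripted cosine trace to its stop", {
    script <- c(0.2, 0.4, 0.6, 0.5, 0.45)
    queried <- integer()
    gen <- function(epoch) {
        queried <<- c(queried, epoch)
        cos_batch(script[epoch / 50])
    }
    mc <- MonitorConfig("cosine_time", epochInterval = 50L, maxEpochs = 500L,
                        patienceChecks = 2L)
    tr <- trainingMonitor(gen, unit_real(), mc)
    expect_equal(stopStep(tr), 250L)
    expect_equal(stopReason(tr), "local_max_patience")
    expect_equal(bestStep(tr), 150L)
    expect_equal(checkpoints(tr)$mean, script, tolerance = 1e-12)
    # the generator is only ever queried on the checkpoint grid
    expect_equal(queried, seq(50L, 250L, 50L))
})

test_that("the training monitor stops at the second checkpoint on perfect batches", {
    real <- random_set(n = 3, nch = 1, len = 24, seed = 3)
    mc <- MonitorConfig("copt_gak", fake_calibration(c(0.9, 1)),
                        epochInterval = 50L, maxEpochs = 1000L,
                        welch = WelchConfig(16L, 8L))
    tr <- trainingMonitor(function(epoch) real, real, mc)
    expect_equal(stopStep(tr), 100L)
    expect_equal(stopReason(tr), "in_range_rule")
})

test_that("a horizon is reported when no rule ever fires", {
    mc <- MonitorConfig("cosine_time", epochInterval = 50L, maxEpochs = 200L)
    tr <- trainingMonitor(function(epoch) cos_batch(epoch / 1000),
                          unit_real(), mc)
    expect_true(is.na(stopStep(tr)))
    expect_equal(stopReason(tr), "horizon_reached")
    expect_equal(nrow(checkpoints(tr)), 4L)
    expect_equal(bestStep(tr), 200L)
})

test_that("generator failure aborts with the partial trace preserved", {
    gen <- function(epoch) {
        if (epoch > 100) stop("model exploded")
        cos_batch(0.5)
    }
    mc <- MonitorConfig("cosine_time", epochInterval = 50L, maxEpochs = 500L)
    tr <- suppressMessages(trainingMonitor(gen, unit_real(), mc))
    expect_equal(stopReason(tr), "aborted")
    expect_equal(nrow(checkpoints(tr)), 2L)
    expect_error(trainingMonitor(function(e) stop("dead"), unit_real(), mc),
                 class = "coptgak_input_error")
})

test_that("the denoising monitor stops on the scripted drop and keeps the best batch", {
    script <- c(0.1, 0.3, 0.5, 0.45, 0.4, 0.35)
    sampler <- function(step) cos_batch(script[step / 30])
    mc <- MonitorConfig("cosine_time", denoiseSteps = 180L,
                        denoiseInterval = 30L)
    res <- denoisingMonitor(sampler, unit_real(), mc)
    expect_equal(stopStep(res$trace), 150L)
    expect_equal(stopReason(res$trace), "two_consecutive_drops")
    expect_equal(bestStep(res$trace), 90L)
    # the returned batch is the one sampled at the best step
    best <- multichannelScore(sequences(res$batch)[[1]],
                              sequences(unit_real())[[1]],
                              "cosine", "time")$averaged
    expect_equal(best, 0.5, tolerance = 1e-12)
})

test_that("flat or rising denoising traces run to the horizon; exhaustion is a horizon", {
    mc <- MonitorConfig("cosine_time", denoiseSteps = 150L,
                        denoiseInterval = 30L)
    rising <- denoisingMonitor(function(step) cos_batch(step / 200),
                               unit_real(), mc)
    expect_equal(stopReason(rising$trace), "horizon_reached")
    expect_equal(bestStep(rising$trace), 150L)
    flat <- denoisingMonitor(function(step) cos_batch(0.4), unit_real(), mc)
    expect_equal(stopReason(flat$trace), "horizon_reached")
    exhausted <- denoisingMonitor(function(step)
        if (step > 60) NULL else cos_batch(step / 200), unit_real(), mc)
    expect_equal(stopReason(exhausted$trace), "horizon_reached")
    expect_equal(nrow(checkpoints(exhausted$trace)), 2L)
})

test_that("monitor configuration is validated", {
    expect_error(MonitorConfig("copt_gak"), "GAKCalibration")
    expect_error(MonitorConfig("cosine_psd", inRangeFraction = 2),
                 "inRangeFraction")
    expect_error(MonitorConfig("cosine_psd", epochInterval = 0L),
                 "intervals")
})
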