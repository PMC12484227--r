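test_that("alignment kernel of two identical single points is exactly 1", {
    expect_equal(gakLogUnnormalized(2.5, 2.5, 0.3), 0)
    expect_equal(gakNormalized(2.5, 2.5, 0.3), 1)
})

test_that("DP kernel equals exhaustive path enumeration on short sequences", {
    set.seed(42)
    worst <- 0
    for (rep in 1:40) {
        n <- sample(2:5, 1); m <- sample(2:5, 1)
        x <- rnorm(n); y <- rnorm(m)
        for (sigma in c(0.1, 1, 10)) {
            lbf <- gak_bruteforce_log(x, y, sigma)
            ldp <- gakLogUnnormalized(x, y, sigma)
            worst <- max(worst, abs(ldp - lbf) / max(1, abs(lbf)))
        }
    }
    expect_lt(worst, 1e-9)
})

test_that("the large-bandwidth limit counts alignment paths (Delannoy numbers)", {
    set.seed(1)
    for (cfg in list(c(2, 3), c(3, 13), c(4, 63))) {
        x <- rnorm(cfg[1])
        sigma <- 1e8 * max(abs(diff(range(x))), 1)
        val <- exp(gakLogUnnormalized(x, x, sigma))
        expect_equal(val, cfg[2], tolerance = 1e-6)
    }
})

test_that("normalized score is symmetric, bounded and selective at small sigma", {
    set.seed(7)
    x <- rnorm(20); y <- rnorm(20)
    expect_identical(gakNormalized(x, y, 0.7), gakNormalized(y, x, 0.7))
    for (sigma in c(0.01, 0.5, 5)) {
        th <- gakNormalized(x, y, sigma)
        expect_gte(th, 0); expect_lte(th, 1)
    }
    # high-selectivity regime: independent sequences score near zero
    scores <- vapply(1:100, function(i)
        gakNormalized(rnorm(50), rnorm(50), 0.01), numeric(1))
    expect_lt(max(scores), 0.05)
})

test_that("log-space DP survives tiny bandwidths on long multichannel data", {
    set.seed(3)
    v <- matrix(rnorm(6 * 160), 6)
    for (ch in 1:6) {
        l <- gakLogUnnormalized(v[ch, ], v[(ch %% 6) + 1, ], 7.15e-4)
        expect_true(is.finite(l))
    }
    s1 <- SensorSequence(v, 50); s2 <- SensorSequence(v + rnorm(960, sd = 0.1), 50)
    sc <- multichannelScore(s1, s2, "gak", domain = "time", sigma = 7.15e-4)
    expect_true(all(is.finite(sc$per_channel)))
    expect_true(all(sc$per_channel >= 0 & sc$per_channel <= 1))
})

test_that("unnormalized kernel is non-decreasing in sigma", {
    set.seed(11)
    x <- rnorm(12); y <- rnorm(12)
    grid <- c(0.05, 0.1, 0.5, 1, 5, 50)
    vals <- vapply(grid, function(s) gakLogUnnormalized(x, y, s), numeric(1))
    expect_true(all(diff(vals) >= 0))
})

test_that("bandwidth and input validation errors are raised", {
    expect_error(gakLogUnnormalized(1:3, 1:3, 0),
                 class = "coptgak_parameter_error")
    expect_error(gakLogUnnormalized(1:3, 1:3, -1),
                 class = "coptgak_parameter_error")
    expect_error(gakLogUnnormalized(numeric(0), 1:3, 1),
                 class = "coptgak_input_error")
    expect_error(gakLogUnnormalized(c(1, NA), 1:2, 1),
                 class = "coptgak_input_error")
})

test_that("baseline metrics match hand arithmetic and reject degenerate input", {
    expect_equal(cosineSimilarity(c(1, 2, 3), 2 * c(1, 2, 3)), 1)
    expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
    expect_equal(cosineSimilarity(c(1, 2, 3), c(3, 2, 1)), 10 / 14)
    expect_error(cosineSimilarity(c(0, 0), c(1, 1)),
                 class = "coptgak_input_error")
    expect_equal(pearsonCorrelation(c(1, 2, 3), c(1, 2, 3)), 1)
    expect_equal(pearsonCorrelation(c(1, 2, 3), c(3, 2, 1)), -1)
    expect_error(pearsonCorrelation(c(1, 2, 3), c(2, 2, 2)),
                 class = "coptgak_input_error")
    expect_equal(rmse(c(1, 2), c(1, 2)), 0)
    expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
    set.seed(2); a <- rnorm(10); b <- rnorm(10)
    expect_identical(rmse(a, b), rmse(b, a))
    expect_error(rmse(1:3, 1:4), class = "coptgak_input_error")
})

test_that("multichannel scores average per-channel values", {
    x <- SensorSequence(matrix(rnorm(40), 2), 50)
    sc <- multichannelScore(x, x, "gak", domain = "time", sigma = 1)
    expect_equal(sc$averaged, 1)
    # constructed channel scores: identical channel (cosine 1) plus an
    # orthogonal channel (cosine 0) average to 0.5
    a <- SensorSequence(rbind(c(1, 0, 1, 0), c(1, 0, 0, 0)), 50)
    b <- SensorSequence(rbind(c(1, 0, 1, 0), c(0, 1, 0, 0)), 50)
    sc2 <- multichannelScore(a, b, "cosine", domain = "time")
    expect_equal(unname(sc2$per_channel), c(1, 0))
    expect_equal(sc2$averaged, 0.5)
    bad <- SensorSequence(matrix(rnorm(60), 3), 50)
    expect_error(multichannelScore(x, bad, "cosine", domain = "time"),
                 class = "coptgak_validation_error")
})

test_that("cosine similarity of white-noise PSDs is clearly positive", {
    set.seed(31)
    scores <- vapply(1:100, function(i) {
        a <- SensorSequence(matrix(rnorm(160), 1), 50)
        b <- SensorSequence(matrix(rnorm(160), 1), 50)
        multichannelScore(a, b, "cosine", domain = "psd")$averaged
    }, numeric(1))
    expect_true(all(scores >= 0))   # PSDs are non-negative vectors
    expect_gt(mean(scores), 0.2)
})

test_that("pairwise score matrix identifies best matches consistently", {
    A <- random_set(n = 5, nch = 2, len = 24, seed = 13)
    B <- random_set(n = 7, nch = 2, len = 24, seed = 14, role = "validation")
    for (metric in c("gak", "cosine", "rmse")) {
        pm <- pairwiseScoreMatrix(A, B, metric, domain = "time", sigma = 0.8)
        expect_equal(dim(pm$scores), c(5L, 7L))
        # brute-force recomputation per pair
        for (i in 1:5) for (j in 1:7)
            expect_equal(pm$scores[i, j],
                         multichannelScore(sequences(A)[[i]],
                                           sequences(B)[[j]], metric,
                                           domain = "time",
                                           sigma = 0.8)$averaged,
                         tolerance = 1e-12)
        pick <- if (metric == "rmse") which.min else which.max
        expect_equal(pm$best_match, unname(apply(pm$scores, 1, pick)))
    }
    # self-comparison: unit diagonal and self best-match for gak
    pm <- pairwiseScoreMatrix(A, A, "gak", domain = "psd", sigma = 1,
                              welch = WelchConfig(16L, 8L))
    expect_equal(diag(pm$scores), rep(1, 5))
    expect_equal(pm$best_match, 1:5)
    # 1x1 sets reduce to multichannelScore
    pm1 <- pairwiseScoreMatrix(A[1], B[1], "cosine", domain = "time")
    expect_equal(as.numeric(pm1$scores),
                 multichannelScore(sequences(A)[[1]], sequences(B)[[1]],
                                   "cosine", domain = "time")$averaged)
    expect_error(pairwiseScoreMatrix(SequenceSet(list(), "train"), B, "gak"),
                 class = "coptgak_input_error")
})

test_that("median-heuristic bandwidth matches the hand-worked example", {
    a <- SequenceSet(list(SensorSequence(matrix(c(0, 0), 1), 50)), "train")
    b <- SequenceSet(list(SensorSequence(matrix(c(1, 1), 1), 50)),
                     "validation")
    # all 4 cross-step distances are 1 -> median 1, scaled by sqrt(2)
    expect_equal(medianHeuristicSigma(a, b), sqrt(2))
    expect_error(medianHeuristicSigma(a, a),
                 class = "coptgak_degenerate_error")
    A <- random_set(n = 2, seed = 1); B <- random_set(n = 2, seed = 2)
    expect_gt(medianHeuristicSigma(A, B), 0)
})
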