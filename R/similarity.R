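#' Unnormalized Global Alignment Kernel (log value)
#'
#' Sum over all monotone alignment paths between two univariate sequences
#' of the product of per-step local kernels
#' \eqn{\kappa(a, b) = e^d / (2 - e^d)} with
#' \eqn{d = -(a-b)^2 / (2\sigma^2)}, evaluated by dynamic programming in
#' log space (the product of hundreds of sub-unity kernels underflows
#' otherwise).  Symmetric in its arguments.  As \eqn{\sigma \to \infty}
#' every local kernel tends to 1 and the kernel value tends to the count
#' of monotone lattice paths (a Delannoy number).
#'
#' @param x,y numeric vectors (length >= 1, finite).
#' @param sigma positive bandwidth of the local kernel.
#' @return log of the unnormalized kernel value.
#' @seealso \code{\link{gakNormalized}}
#' @export
gakLogUnnormalized <- function(x, y, sigma) {
    if (length(x) < 1L || length(y) < 1L)
        stopf("sequences must be non-empty", class = "coptgak_input_error")
    if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
        stopf("sequences must be finite", class = "coptgak_input_error")
    if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0 ||
        !is.finite(sigma))
        stopf("sigma must be a single positive finite number",
              class = "coptgak_parameter_error")
    .gak_log_cpp(as.numeric(x), as.numeric(y), sigma)
}

#' Normalized Global Alignment Kernel score
#'
#' \eqn{\vartheta(x, y) = k(x, y) / \sqrt{k(x, x) k(y, y)}}, computed in
#' log space and exponentiated; lies in [0, 1] with
#' \eqn{\vartheta(x, x) = 1}.
#'
#' @inheritParams gakLogUnnormalized
#' @return Similarity score in [0, 1].
#' @examples
#' x <- rnorm(50)
#' gakNormalized(x, x, sigma = 0.5)  # 1
#' @export
gakNormalized <- function(x, y, sigma) {
    lxy <- gakLogUnnormalized(x, y, sigma)
    lxx <- gakLogUnnormalized(x, x, sigma)
    lyy <- gakLogUnnormalized(y, y, sigma)
    min(1, max(0, exp(lxy - 0.5 * (lxx + lyy))))
}

#' Cosine similarity between two vectors
#'
#' \eqn{s_c = x \cdot y / (\|x\| \|y\|)} in [-1, 1].
#'
#' @param x,y numeric vectors of equal length, neither all-zero.
#' @return Cosine similarity.
#' @export
cosineSimilarity <- function(x, y) {
    if (length(x) != length(y))
        stopf("length mismatch", class = "coptgak_input_error")
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0)
        stopf("cosine similarity undefined for zero-norm input",
              class = "coptgak_input_error")
    sum(x * y) / (nx * ny)
}

#' Pearson correlation between two vectors
#'
#' @param x,y numeric vectors of equal length >= 2, neither constant.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearsonCorrelation <- function(x, y) {
    if (length(x) != length(y) || length(x) < 2L)
        stopf("need equal lengths >= 2", class = "coptgak_input_error")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stopf("Pearson correlation undefined for constant input",
              class = "coptgak_input_error")
    stats::cor(x, y)
}

#' Root-mean-square error between two vectors
#'
#' @param x,y numeric vectors of equal length.
#' @return \eqn{\sqrt{\sum_i (x_i - y_i)^2 / n}} (>= 0; 0 iff identical).
#' @export
rmse <- function(x, y) {
    if (length(x) != length(y))
        stopf("length mismatch", class = "coptgak_input_error")
    sqrt(mean((x - y)^2))
}

metric_fun <- function(metric, sigma) {
    switch(metric,
        gak     = function(x, y) gakNormalized(x, y, sigma),
        cosine  = cosineSimilarity,
        pearson = pearsonCorrelation,
        rmse    = rmse,
        stopf("unknown metric '%s'", metric, class = "coptgak_parameter_error"))
}

# channel matrices (channels x len) for a single Sequence/PSDVector
single_domain_matrix <- function(obj, domain, config) {
    if (is(obj, "PSDVector")) return(obj@power)
    if (domain == "psd") welchPSD(obj, config)@power else seqValues(obj)
}

#' Per-channel similarity score with channel averaging
#'
#' Applies the chosen metric independently to every channel of the two
#' inputs — in the time domain or on their Welch PSDs — and reports both
#' the per-channel scores and their arithmetic mean, the study's
#' multichannel aggregation.
#'
#' @param X,Y both \linkS4class{SensorSequence} or both
#'   \linkS4class{PSDVector}, with matching channel geometry.
#' @param metric one of \code{"gak"}, \code{"cosine"}, \code{"pearson"},
#'   \code{"rmse"}.
#' @param domain \code{"psd"} (default) or \code{"time"}; ignored when the
#'   inputs are already PSDs.
#' @param sigma GAK bandwidth (required for \code{metric = "gak"}).
#' @param welch \linkS4class{WelchConfig} for on-the-fly PSDs.
#' @return List with elements \code{metric}, \code{domain},
#'   \code{per_channel} (named numeric) and \code{averaged}.
#' @export
multichannelScore <- function(X, Y, metric = c("gak", "cosine", "pearson",
                                               "rmse"),
                              domain = c("psd", "time"), sigma = NULL,
                              welch = WelchConfig()) {
    metric <- match.arg(metric); domain <- match.arg(domain)
    if (is(X, "PSDVector")) domain <- "psd"
    mx <- single_domain_matrix(X, domain, welch)
    my <- single_domain_matrix(Y, domain, welch)
    if (nrow(mx) != nrow(my) || ncol(mx) != ncol(my))
        stopf("channel geometry mismatch (%dx%d vs %dx%d)",
              nrow(mx), ncol(mx), nrow(my), ncol(my),
              class = "coptgak_validation_error")
    if (metric == "gak" && is.null(sigma))
        stopf("metric 'gak' requires sigma", class = "coptgak_parameter_error")
    f <- metric_fun(metric, sigma)
    per <- vapply(seq_len(nrow(mx)), function(ch) f(mx[ch, ], my[ch, ]),
                  numeric(1))
    names(per) <- rownames(mx) %||% paste0("ch", seq_along(per))
    list(metric = metric, domain = domain, per_channel = per,
         averaged = mean(per))
}

# Averaged-channel normalized GAK score matrix between two sets, using the
# fast C++ cross-kernel on pre-extracted channel matrices.
gak_score_matrix_from_mats <- function(matsA, matsB, sigma) {
    nA <- ncol(matsA[[1]]); nB <- ncol(matsB[[1]])
    acc <- matrix(0, nA, nB)
    for (ch in seq_along(matsA)) {
        cross <- .gak_cross_log_cpp(matsA[[ch]], matsB[[ch]], sigma)
        selfA <- .gak_self_log_cpp(matsA[[ch]], sigma)
        selfB <- .gak_self_log_cpp(matsB[[ch]], sigma)
        th <- exp(cross - 0.5 * outer(selfA, selfB, "+"))
        acc <- acc + pmin(1, pmax(0, th))
    }
    acc / length(matsA)
}

#' Pairwise similarity matrix between two sequence sets
#'
#' Scores every pair (one sequence from \code{A}, one from \code{B}) with
#' the averaged-channel metric and identifies, per row, the most similar
#' partner in \code{B} (argmax for gak/cosine/pearson, argmin for rmse;
#' ties broken by lowest index).
#'
#' @param A,B non-empty \linkS4class{SequenceSet}s with matching channel
#'   geometry.
#' @inheritParams multichannelScore
#' @return List with \code{scores} (|A| x |B| matrix) and
#'   \code{best_match} (integer vector, per row of \code{A}).
#' @export
pairwiseScoreMatrix <- function(A, B, metric = c("gak", "cosine", "pearson",
                                                 "rmse"),
                                domain = c("psd", "time"), sigma = NULL,
                                welch = WelchConfig()) {
    metric <- match.arg(metric); domain <- match.arg(domain)
    if (nSequences(A) == 0L || nSequences(B) == 0L)
        stopf("sets must be non-empty", class = "coptgak_input_error")
    if (!identical(channelNames(A), channelNames(B)))
        stopf("channel geometry mismatch between sets",
              class = "coptgak_validation_error")
    matsA <- domain_matrices(A, domain, welch)
    matsB <- domain_matrices(B, domain, welch)
    if (metric == "gak") {
        if (is.null(sigma))
            stopf("metric 'gak' requires sigma", class = "coptgak_parameter_error")
        scores <- gak_score_matrix_from_mats(matsA, matsB, sigma)
    } else {
        f <- metric_fun(metric, sigma)
        nA <- ncol(matsA[[1]]); nB <- ncol(matsB[[1]])
        scores <- matrix(0, nA, nB)
        for (i in seq_len(nA)) for (j in seq_len(nB))
            scores[i, j] <- mean(vapply(seq_along(matsA), function(ch)
                f(matsA[[ch]][, i], matsB[[ch]][, j]), numeric(1)))
    }
    pick <- if (metric == "rmse") which.min else which.max
    best <- apply(scores, 1L, pick)
    list(scores = scores, best_match = as.integer(best), metric = metric,
         domain = domain)
}

#' Median-heuristic GAK bandwidth (literature baseline)
#'
#' The classical bandwidth rule: the median Euclidean distance between
#' timestep observations drawn across the two sets, scaled by the square
#' root of the median sequence length.  Provided as the baseline that the
#' class-optimized calibration replaces; on narrowly varying activity data
#' it yields very small bandwidths (order 1e-3 and below), i.e. a degree
#' of selectivity at which nearly all scores collapse toward 0.
#'
#' @param A,B non-empty \linkS4class{SequenceSet}s.
#' @param maxSteps subsample cap on timesteps per set (for large inputs).
#' @return Positive bandwidth.
#' @export
medianHeuristicSigma <- function(A, B, maxSteps = 2000L) {
    if (nSequences(A) == 0L || nSequences(B) == 0L)
        stopf("sets must be non-empty", class = "coptgak_input_error")
    step_cols <- function(set) {
        m <- do.call(cbind, lapply(sequences(set), seqValues))  # ch x steps
        if (ncol(m) > maxSteps)
            m <- m[, round(seq(1, ncol(m), length.out = maxSteps)), drop = FALSE]
        m
    }
    ma <- step_cols(A); mb <- step_cols(B)
    # squared cross distances between timestep column vectors
    d2 <- outer(colSums(ma^2), colSums(mb^2), "+") - 2 * crossprod(ma, mb)
    med <- stats::median(sqrt(pmax(d2, 0)))
    if (med <= 0)
        stopf("median timestep distance is zero (degenerate input); %s",
              "no usable bandwidth", class = "coptgak_degenerate_error")
    lens <- c(vapply(sequences(A), seqLength, integer(1)),
              vapply(sequences(B), seqLength, integer(1)))
    med * sqrt(stats::median(lens))
}
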