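#' @useDynLib coptgak, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

.LOG_LEVELS <- c(debug = 10L, info = 20L, warn = 30L, error = 40L)

#' Set the package log level
#'
#' Structured log lines have the form
#' \code{<ISO time> <LEVEL> <module> <message>} and are emitted via
#' \code{message()}.  Monitor checkpoints are always logged at \code{info}.
#'
#' @param level One of \code{"debug"}, \code{"info"}, \code{"warn"},
#'   \code{"error"}.
#' @return The previous level, invisibly.
#' @export
setLogLevel <- function(level = c("info", "debug", "warn", "error")) {
    level <- match.arg(level)
    old <- getOption("coptgak.log_level", "info")
    options(coptgak.log_level = level)
    invisible(old)
}

cklog <- function(level, module, msg) {
    thr <- .LOG_LEVELS[[getOption("coptgak.log_level", "info")]]
    if (.LOG_LEVELS[[level]] < thr) return(invisible(NULL))
    message(sprintf("%s %s %s %s",
                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    toupper(level), module, msg))
    invisible(NULL)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# Derive a distinct, well-separated 31-bit sub-seed from a base seed and a
# stream tag (polynomial string hash mixed with the base seed; tags that
# differ in one character map to distant seeds).
derive_seed <- function(seed, tag) {
    h <- 0
    for (ch in utf8ToInt(as.character(tag)))
        h <- (h * 131 + ch) %% 2147483629
    h <- (h * 48271) %% 2147483629
    as.integer(((as.numeric(seed) %% 65521) * 32749 + h) %% 2147483647)
}

stopf <- function(fmt, ..., class = "coptgak_error") {
    stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}
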