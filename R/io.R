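#' Save a SequenceSet to disk
#'
#' Two on-disk dialects are supported: \code{"csv"} — a diff-friendly long
#' table with columns \code{sequence_id, subject_id, class_label, channel,
#' t, value, sample_rate_hz} — and \code{"rds"} — R's native lossless
#' serialization of the S4 object.  CSV roundtrips within 1e-12 per
#' element; RDS roundtrips exactly.
#'
#' @param set a non-empty \linkS4class{SequenceSet}.
#' @param path output file path.
#' @param format \code{"csv"} or \code{"rds"}; default inferred from the
#'   file extension.
#' @return \code{path}, invisibly.
#' @export
saveSequenceSet <- function(set, path, format = c("auto", "csv", "rds")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "csv"
    stopifnot(is(set, "SequenceSet"))
    if (nSequences(set) == 0L)
        stopf("refusing to save an empty SequenceSet", class = "coptgak_input_error")
    if (format == "rds") {
        saveRDS(set, path)
        return(invisible(path))
    }
    tabs <- lapply(seq_len(nSequences(set)), function(i) {
        s <- sequences(set)[[i]]
        v <- seqValues(s)
        data.table::data.table(
            sequence_id = i,
            subject_id = subjectId(s),
            class_label = classLabel(s),
            channel = rep(channelNames(s), each = ncol(v)),
            t = rep(seq_len(ncol(v)) - 1L, times = nrow(v)),
            value = as.vector(t(v)),
            sample_rate_hz = sampleRate(s))
    })
    data.table::fwrite(data.table::rbindlist(tabs), path)
    invisible(path)
}

#' Load a SequenceSet from disk
#'
#' Inverse of \code{\link{saveSequenceSet}}.  Sequence and channel order is
#' preserved exactly as stored; ragged channels or missing values are
#' rejected with the offending sequence named.
#'
#' @param path input file path.
#' @param format \code{"csv"} or \code{"rds"}; default inferred from the
#'   extension.
#' @param role pipeline role to stamp on the loaded set.
#' @return A \linkS4class{SequenceSet}.
#' @export
loadSequenceSet <- function(path, format = c("auto", "csv", "rds"),
                            role = "train") {
    format <- match.arg(format)
    if (!file.exists(path))
        stopf("file not found: %s", path, class = "coptgak_input_error")
    if (format == "auto")
        format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "csv"
    if (format == "rds") {
        set <- readRDS(path)
        if (!is(set, "SequenceSet"))
            stopf("%s does not contain a SequenceSet", path,
                  class = "coptgak_input_error")
        validObject(set)
        return(set)
    }
    if (file.size(path) == 0)
        stopf("empty file: %s", path, class = "coptgak_input_error")
    tab <- tryCatch(data.table::fread(path),
                    error = function(e) stopf("cannot parse %s: %s", path,
                                              conditionMessage(e),
                                              class = "coptgak_input_error"))
    need <- c("sequence_id", "subject_id", "class_label", "channel", "t",
              "value", "sample_rate_hz")
    if (nrow(tab) == 0L)
        stopf("empty file: %s", path, class = "coptgak_input_error")
    if (!all(need %in% names(tab)))
        stopf("%s lacks required columns: %s", path,
              paste(setdiff(need, names(tab)), collapse = ", "),
              class = "coptgak_input_error")
    ids <- unique(tab$sequence_id)        # order of first appearance
    seqs <- lapply(ids, function(id) {
        sub <- tab[tab$sequence_id == id, ]
        chans <- unique(sub$channel)      # stored channel order
        lens <- vapply(chans, function(ch) sum(sub$channel == ch), integer(1))
        if (length(unique(lens)) != 1L)
            stopf("sequence %s has ragged channel lengths", id,
                  class = "coptgak_validation_error")
        if (anyNA(sub$value))
            stopf("sequence %s contains missing values", id,
                  class = "coptgak_validation_error")
        vals <- do.call(rbind, lapply(chans, function(ch) {
            rows <- sub[sub$channel == ch, ]
            rows$value[order(rows$t)]
        }))
        tryCatch(
            SensorSequence(vals, sampleRate = sub$sample_rate_hz[1],
                           channelNames = as.character(chans),
                           classLabel = as.character(sub$class_label[1]),
                           subjectId = as.character(sub$subject_id[1])),
            error = function(e) stopf("sequence %s invalid: %s", id,
                                      conditionMessage(e),
                                      class = "coptgak_validation_error"))
    })
    SequenceSet(seqs, role = role)
}

#' Serialize a GAKCalibration to JSON (including the full sweep)
#'
#' @param calib a \linkS4class{GAKCalibration}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeCalibration <- function(calib, path) {
    obj <- list(sigma_opt = calib@sigmaOpt, mean_score = calib@meanScore,
                std_score = calib@stdScore, std_range = calib@stdRange,
                acceptance_range = calib@acceptanceRange,
                aggregation = calib@aggregation,
                class_label = calib@classLabel,
                subject_scope = calib@subjectScope,
                sweep = calib@sweep)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeCalibration
#' @return \code{readCalibration}: the \linkS4class{GAKCalibration}.
#' @export
readCalibration <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("GAKCalibration", sigmaOpt = obj$sigma_opt,
        meanScore = obj$mean_score, stdScore = obj$std_score,
        stdRange = as.numeric(obj$std_range),
        acceptanceRange = as.numeric(obj$acceptance_range),
        sweep = as.data.frame(obj$sweep), aggregation = obj$aggregation,
        classLabel = obj$class_label, subjectScope = obj$subject_scope)
}

#' Serialize a MonitorTrace to JSON
#'
#' @param trace a \linkS4class{MonitorTrace}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeMonitorTrace <- function(trace, path) {
    obj <- list(checkpoints = trace@checkpoints,
                scores = trace@scores,
                stop_step = if (is.na(trace@stopStep)) NULL else trace@stopStep,
                best_step = trace@bestStep,
                stop_reason = trace@stopReason,
                seed = trace@seed)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
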