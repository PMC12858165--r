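# Readers and writers for the external formats: signals (EDF or numeric
# binary + JSON sidecar, optionally a BIDS-iEEG layout), events / feature /
# subject TSV tables, and the serialized results.

#' Read a channel table
#'
#' @param path TSV with columns \code{name}, \code{region},
#'   \code{hemisphere}, \code{status}.
#' @return validated data.frame.
#' @export
readChannelTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("name", "region", "hemisphere", "status")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("channel table misses column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(tab$name))
        stop("duplicate channel names: ",
             paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
    if (!all(tab$region %in% c("DLPFC", "pSTC", "other")))
        stop("region must be one of DLPFC, pSTC, other")
    if (!all(tab$status %in% c("good", "bad")))
        stop("status must be good or bad")
    tab[need]
}

defaultChannelTable <- function(names) {
    data.frame(name = names, region = "other",
               hemisphere = "L", status = "good",
               stringsAsFactors = FALSE)
}

#' Read a multichannel recording
#'
#' Accepts either an EDF file (extension \code{.edf}) or a raw numeric
#' binary (little-endian float64, column-major samples x channels) with a
#' JSON sidecar \code{<path>.json} declaring \code{fs}, \code{channel_names}
#' and \code{dtype}. A channel table may be attached; its names must match
#' the signal channel names exactly (bad channels are retained but
#' flagged).
#'
#' @param path signal file.
#' @param channel_table_path optional TSV channel table
#'   (see [readChannelTable()]).
#' @param subject optional named list of subject metadata.
#' @return an [IeegRecording-class] object.
#' @export
readRecording <- function(path, channel_table_path = NULL, subject = list()) {
    ext <- tolower(tools::file_ext(path))
    if (ext == "edf") {
        sig <- readEDF(path)
    } else if (ext %in% c("bin", "dat")) {
        sidecar <- paste0(path, ".json")
        if (!file.exists(sidecar))
            stop("format error: sidecar not found: ", sidecar)
        meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
        if (is.null(meta$fs) || !is.numeric(meta$fs) || meta$fs <= 0)
            stop("sidecar fs must be a positive number")
        if (!identical(meta$dtype, "float64"))
            stop("format error: unsupported dtype: ", meta$dtype)
        nch <- length(meta$channel_names)
        vals <- readBin(path, "double", n = file.size(path) / 8L,
                        size = 8L, endian = "little")
        if (length(vals) %% nch != 0L)
            stop("binary length not a multiple of the channel count")
        data <- matrix(vals, ncol = nch)
        colnames(data) <- meta$channel_names
        sig <- list(data = data, fs = meta$fs,
                    channel_names = meta$channel_names)
    } else {
        stop("format error: unknown signal format: .", ext)
    }
    if (!is.null(channel_table_path)) {
        ch <- if (is.character(channel_table_path))
            readChannelTable(channel_table_path) else channel_table_path
        extra <- setdiff(ch$name, sig$channel_names)
        absent <- setdiff(sig$channel_names, ch$name)
        if (length(extra) || length(absent))
            stop("metadata error: channel name mismatch; ",
                 if (length(extra)) paste0("in table only: ",
                     paste(extra, collapse = ", "), "; ") else "",
                 if (length(absent)) paste0("in signal only: ",
                     paste(absent, collapse = ", ")) else "")
        ch <- ch[match(sig$channel_names, ch$name), , drop = FALSE]
        rownames(ch) <- NULL
    } else {
        ch <- defaultChannelTable(sig$channel_names)
    }
    new("IeegRecording", data = sig$data, fs = sig$fs, channels = ch,
        subject = subject, unit = "signal")
}

#' Write a recording as numeric binary + JSON sidecar
#'
#' @param rec an [IeegRecording-class] object.
#' @param path output path (conventionally \code{.bin}); the sidecar is
#'   written to \code{<path>.json}.
#' @return invisibly, \code{path}.
#' @export
writeRecordingBinary <- function(rec, path) {
    writeBin(as.numeric(rec@data), path, size = 8L, endian = "little")
    meta <- list(fs = rec@fs, channel_names = rec@channels$name,
                 dtype = "float64", n_samples = nrow(rec@data))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' Read an events table
#'
#' @param path TSV with columns \code{onset}, \code{duration},
#'   \code{trial_type} (or \code{condition}) and \code{block_index}.
#' @return data.frame sorted by onset with columns onset, duration,
#'   condition, block_index; blocks validated as non-overlapping with
#'   conditions in \{speech, music\}.
#' @export
readEvents <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"condition" %in% names(tab) && "trial_type" %in% names(tab))
        names(tab)[names(tab) == "trial_type"] <- "condition"
    need <- c("onset", "duration", "condition", "block_index")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("events table misses column(s): ", paste(miss, collapse = ", "))
    tab <- tab[order(tab$onset), need]
    rownames(tab) <- NULL
    validateEvents(tab)
    tab
}

validateEvents <- function(ev) {
    if (!all(ev$condition %in% c("speech", "music")))
        stop("condition outside {speech, music}: ",
             paste(setdiff(unique(ev$condition), c("speech", "music")),
                   collapse = ", "))
    if (any(ev$duration <= 0)) stop("block durations must be positive")
    if (anyDuplicated(ev$block_index)) stop("duplicate block_index")
    if (nrow(ev) > 1L) {
        ends <- ev$onset + ev$duration
        if (any(ev$onset[-1L] < ends[-nrow(ev)] - 1e-9))
            stop("blocks overlap in time")
    }
    invisible(ev)
}

#' Read a raw feature table
#'
#' @param path TSV with a \code{time} column (seconds from recording
#'   start), optionally a \code{face_id} column, and one column per
#'   configured emotion name.
#' @param feature_names expected feature columns.
#' @return data.frame with time (and face_id if present) followed by the
#'   feature columns in configured order; values validated to \eqn{[0, 1]}.
#' @export
readFeatureTable <- function(path, feature_names = emotionVocabulary()) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (!"time" %in% names(tab)) stop("feature table misses column: time")
    miss <- setdiff(feature_names, names(tab))
    if (length(miss))
        stop("feature table misses feature column(s): ",
             paste(miss, collapse = ", "))
    vals <- as.matrix(tab[feature_names])
    if (any(!is.finite(vals)) || min(vals) < 0 || max(vals) > 1)
        stop("feature scores must be finite and in [0, 1]")
    keep <- c("time", intersect("face_id", names(tab)), feature_names)
    tab[keep]
}

#' Read a subject table
#'
#' @param path TSV with columns \code{id}, \code{age}, \code{group}
#'   (\code{childhood}/\code{post_childhood}) and optionally \code{sex}.
#' @return validated data.frame.
#' @export
readSubjects <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("id", "age", "group")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("subject table misses column(s): ", paste(miss, collapse = ", "))
    if (!all(tab$group %in% c("childhood", "post_childhood")))
        stop("group must be childhood or post_childhood")
    if (any(!is.finite(tab$age) | tab$age <= 0))
        stop("ages must be positive numbers")
    if (anyDuplicated(tab$id)) stop("duplicate subject ids")
    tab
}

#' Read a minimal BIDS-iEEG subject directory
#'
#' Looks for \code{*_ieeg.edf} (or \code{.bin}), \code{*_channels.tsv} and
#' \code{*_events.tsv} under \code{dir} and assembles a recording plus
#' events. The channels.tsv \code{status} column and a \code{region} column
#' (non-standard but accepted) are mapped onto the channel table.
#'
#' @param dir directory containing the three files.
#' @param subject optional subject metadata list.
#' @return list with elements \code{recording} and \code{events}.
#' @export
readBIDSiEEG <- function(dir, subject = list()) {
    sig <- list.files(dir, "_ieeg\\.(edf|bin)$", full.names = TRUE)
    chf <- list.files(dir, "_channels\\.tsv$", full.names = TRUE)
    evf <- list.files(dir, "_events\\.tsv$", full.names = TRUE)
    if (length(sig) != 1L || length(evf) != 1L)
        stop("expected exactly one *_ieeg signal and one *_events.tsv in ",
             dir)
    ch <- NULL
    if (length(chf) == 1L) {
        tab <- utils::read.delim(chf, stringsAsFactors = FALSE)
        ch <- data.frame(
            name = tab$name,
            region = if ("region" %in% names(tab)) tab$region else "other",
            hemisphere = if ("hemisphere" %in% names(tab))
                tab$hemisphere else "L",
            status = if ("status" %in% names(tab)) tab$status else "good",
            stringsAsFactors = FALSE)
    }
    rec <- readRecording(sig, channel_table_path = ch, subject = subject)
    list(recording = rec, events = readEvents(evf))
}

fitToList <- function(fit, perm = NULL) {
    out <- list(subject = fit@subject, region = fit@region,
                condition = fit@condition, alpha = fit@alpha,
                fold_r = round(fit@foldR, 6L),
                mean_r = if (is.finite(fit@meanR))
                    round(fit@meanR, 6L) else NULL,
                n_rows = fit@nRows, n_contacts = fit@nContacts)
    if (!is.null(perm)) {
        out$perm_p <- round(perm@p, 6L)
        out$n_perm <- perm@nPerm
    }
    out
}

#' Serialize analysis results
#'
#' Writes a deterministic snapshot of an analysis: \code{results.json}
#' (per-fit alpha, per-fold r, mean r, permutation p where available, plus
#' the configuration and seed for provenance), \code{weights.tsv}
#' (subjects x features) and \code{group_stats.json}. Keys are sorted and
#' floats written at fixed precision so identical inputs give byte-identical
#' files. Non-finite accuracies are serialized as \code{null} with a
#' warning.
#'
#' @param fits list of [EncodingFit-class] objects.
#' @param weight_table data.frame from [weightTable()], or NULL.
#' @param group_stats list/data.frame of group statistics, or NULL.
#' @param dir output directory (created if needed).
#' @param config the [PipelineConfig-class] used.
#' @param perms optional list of [PermutationResult-class] parallel to
#'   \code{fits}.
#' @return invisibly, the paths written.
#' @export
writeResults <- function(fits, weight_table = NULL, group_stats = NULL,
                         dir = ".", config = pipelineConfig(),
                         perms = NULL) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    if (any(!vapply(fits, function(f) is.finite(f@meanR), TRUE)))
        warning("non-finite mean accuracies serialized as null")
    recs <- lapply(seq_along(fits), function(i)
        fitToList(fits[[i]], if (is.null(perms)) NULL else perms[[i]]))
    keys <- vapply(fits, function(f)
        paste(f@subject, f@region, f@condition, sep = "."), "")
    recs <- recs[order(keys)]
    names(recs) <- sort(keys)
    cfg <- lapply(slotNames(config), function(s) slot(config, s))
    names(cfg) <- slotNames(config)
    cfg <- cfg[order(names(cfg))]
    out <- list(config = cfg, seed = config@rng_seed, fits = recs)
    fjson <- file.path(dir, "results.json")
    jsonlite::write_json(out, fjson, auto_unbox = TRUE, digits = 8L,
                         pretty = TRUE, null = "null", na = "null")
    paths <- fjson
    if (!is.null(weight_table)) {
        ftsv <- file.path(dir, "weights.tsv")
        num <- vapply(weight_table, is.numeric, TRUE)
        weight_table[num] <- lapply(weight_table[num], function(x)
            signif(x, 10L))
        utils::write.table(weight_table, ftsv, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths <- c(paths, ftsv)
    }
    if (!is.null(group_stats)) {
        fgs <- file.path(dir, "group_stats.json")
        if (is.data.frame(group_stats))
            group_stats <- split(group_stats, seq_len(nrow(group_stats)))
        jsonlite::write_json(group_stats, fgs, auto_unbox = TRUE,
                             digits = 8L, pretty = TRUE, na = "null")
        paths <- c(paths, fgs)
    }
    invisible(paths)
}
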