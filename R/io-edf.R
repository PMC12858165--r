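# Minimal reader/writer for continuous European Data Format (EDF) files.
# Supports the plain-EDF subset: one uniform sampling rate across signals,
# contiguous data records, 16-bit samples. No installed package provides an
# EDF parser, so the format is handled here directly.

edfString <- function(con, n) {
    trimws(rawToChar(readBin(con, "raw", n)))
}

padField <- function(x, width) {
    x <- substr(as.character(x), 1L, width)
    formatC(x, width = width, flag = "-")
}

#' Read a continuous EDF file
#'
#' Parses the plain-EDF subset used for clinical time series: a global
#' header, one 256-byte metadata block per signal, and contiguous records of
#' little-endian 16-bit integers which are mapped to physical units via the
#' per-signal digital/physical ranges. All signals must share one sampling
#' rate.
#'
#' @param path path to an \code{.edf} file.
#' @return list with elements \code{data} (samples x channels matrix in
#'   physical units), \code{fs} (Hz) and \code{channel_names}.
#' @seealso [readRecording()] which attaches a channel table.
#' @export
readEDF <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    version <- edfString(con, 8L)
    if (!identical(version, "0"))
        stop("unsupported EDF version field: ", version)
    invisible(edfString(con, 80L))            # patient id
    invisible(edfString(con, 80L))            # recording id
    invisible(edfString(con, 8L))             # start date
    invisible(edfString(con, 8L))             # start time
    invisible(edfString(con, 8L))             # header bytes
    reserved <- edfString(con, 44L)
    if (grepl("EDF\\+D", reserved))
        stop("discontinuous EDF+ files are not supported")
    n_rec <- as.integer(edfString(con, 8L))
    rec_dur <- as.numeric(edfString(con, 8L))
    ns <- as.integer(edfString(con, 4L))
    if (is.na(ns) || ns < 1L) stop("EDF header declares no signals")
    if (is.na(rec_dur) || rec_dur <= 0)
        stop("EDF record duration must be positive")
    labels <- vapply(seq_len(ns), function(i) edfString(con, 16L), "")
    invisible(readBin(con, "raw", 80L * ns))  # transducer
    invisible(readBin(con, "raw", 8L * ns))   # physical dimension
    pmin_ <- as.numeric(vapply(seq_len(ns), function(i) edfString(con, 8L), ""))
    pmax_ <- as.numeric(vapply(seq_len(ns), function(i) edfString(con, 8L), ""))
    dmin_ <- as.numeric(vapply(seq_len(ns), function(i) edfString(con, 8L), ""))
    dmax_ <- as.numeric(vapply(seq_len(ns), function(i) edfString(con, 8L), ""))
    invisible(readBin(con, "raw", 80L * ns))  # prefiltering
    spr <- as.integer(vapply(seq_len(ns), function(i) edfString(con, 8L), ""))
    invisible(readBin(con, "raw", 32L * ns))  # reserved
    keep <- !grepl("annotation", labels, ignore.case = TRUE)
    if (length(unique(spr)) != 1L)
        stop("signals with differing sampling rates are not supported")
    fs <- spr[keep][1L] / rec_dur
    total <- sum(spr)
    raw16 <- readBin(con, "integer", n = n_rec * total, size = 2L,
                     signed = TRUE, endian = "little")
    if (length(raw16) < n_rec * total)
        stop("EDF file truncated: expected ", n_rec * total, " samples")
    cube <- array(raw16, dim = c(spr[1L], ns, n_rec))  # uniform spr assumed
    gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
    data <- matrix(0, nrow = spr[1L] * n_rec, ncol = sum(keep))
    col <- 0L
    for (i in seq_len(ns)) {
        if (!keep[i]) next
        col <- col + 1L
        dig <- as.numeric(cube[, i, ])
        data[, col] <- gain[i] * (dig - dmin_[i]) + pmin_[i]
    }
    colnames(data) <- labels[keep]
    list(data = data, fs = fs, channel_names = labels[keep])
}

#' Write a continuous EDF file
#'
#' Companion writer for [readEDF()], used mainly to materialize synthetic
#' recordings on disk. Samples are quantized to the 16-bit digital range
#' per channel. The sampling rate times the record duration must be an
#' integer number of samples per record.
#'
#' @param data samples x channels numeric matrix.
#' @param fs sampling rate, Hz.
#' @param path output path.
#' @param channel_names optional channel labels (default from colnames).
#' @param record_duration record length in seconds (default chosen so that
#'   samples per record is integer).
#' @return invisibly, the path written.
#' @export
writeEDF <- function(data, fs, path, channel_names = colnames(data),
                     record_duration = 1) {
    data <- as.matrix(data)
    ns <- ncol(data)
    if (is.null(channel_names))
        channel_names <- paste0("ch", seq_len(ns))
    spr <- fs * record_duration
    if (abs(spr - round(spr)) > 1e-9)
        stop("fs * record_duration must be an integer")
    spr <- as.integer(round(spr))
    n_rec <- ceiling(nrow(data) / spr)
    if (n_rec * spr > nrow(data))    # zero-pad the final partial record
        data <- rbind(data, matrix(0, n_rec * spr - nrow(data), ns))
    pmax_ <- apply(abs(data), 2L, max)
    pmax_[pmax_ == 0] <- 1
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- paste0(padField("0", 8L), padField("X", 80L), padField("X", 80L),
                  padField("01.01.26", 8L), padField("00.00.00", 8L),
                  padField(256L * (1L + ns), 8L), padField("", 44L),
                  padField(n_rec, 8L), padField(record_duration, 8L),
                  padField(ns, 4L))
    writeChar(hdr, con, eos = NULL)
    fields <- list(
        vapply(channel_names, padField, "", width = 16L),
        rep(padField("", 80L), ns),
        rep(padField("uV", 8L), ns),
        vapply(-pmax_, padField, "", width = 8L),
        vapply(pmax_, padField, "", width = 8L),
        rep(padField(-32767L, 8L), ns),
        rep(padField(32767L, 8L), ns),
        rep(padField("", 80L), ns),
        rep(padField(spr, 8L), ns),
        rep(padField("", 32L), ns))
    for (f in fields) writeChar(paste0(f, collapse = ""), con, eos = NULL)
    dig <- matrix(0L, nrow(data), ns)
    for (j in seq_len(ns))
        dig[, j] <- as.integer(round(data[, j] / pmax_[j] * 32767))
    cube <- array(dig, dim = c(spr, n_rec, ns))
    cube <- aperm(cube, c(1L, 3L, 2L))       # samples x signals x records
    writeBin(as.integer(cube), con, size = 2L, endian = "little")
    invisible(path)
}
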