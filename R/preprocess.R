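# Raw signal -> normalized per-block HFB amplitude epochs.
#
# The chain is: notch -> common average reference -> band-pass + analytic
# amplitude -> epoch blocks (with a pre-onset baseline margin) -> downsample
# -> square root -> baseline z-score. All filters are applied zero-phase
# (forward-backward), which preserves envelope timing relative to the
# stimulus at the cost of doubling the effective filter order.

#' Remove power-line interference
#'
#' Applies a second-order IIR notch (quality factor from the configuration,
#' default 30) at the line frequency, zero-phase, to every channel.
#' Only the fundamental is removed.
#'
#' @param rec an [IeegRecording-class] object.
#' @param line_freq line frequency, Hz; must be below Nyquist.
#' @param q notch quality factor (bandwidth = line_freq / q).
#' @return the filtered recording.
#' @export
notchFilter <- function(rec, line_freq = 50, q = 30) {
    if (line_freq >= rec@fs / 2)
        stop("line_freq must be below the Nyquist frequency")
    nf <- designNotch(line_freq, rec@fs, q)
    filt <- signal::Arma(b = nf$b, a = nf$a)
    rec@data <- filtfiltMatrix(filt, rec@data)
    rec
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean across good channels from every
#' channel. Channels flagged bad are excluded from the reference but are
#' themselves re-referenced.
#'
#' @param rec an [IeegRecording-class] object.
#' @return the re-referenced recording.
#' @export
commonAverageReference <- function(rec) {
    good <- rec@channels$status == "good"
    if (sum(good) < 2L)
        stop("common average reference needs at least 2 good channels")
    ref <- rowMeans(rec@data[, good, drop = FALSE])
    rec@data <- rec@data - ref
    rec
}

#' Extract high-frequency-band analytic amplitude
#'
#' Band-pass filters each channel (Butterworth, zero-phase) and takes the
#' modulus of the analytic signal (Hilbert construction): the instantaneous
#' envelope of the band-limited activity.
#'
#' @param rec an [IeegRecording-class] object.
#' @param band two band edges in Hz, inside (0, fs/2).
#' @param order Butterworth order (effective order doubles zero-phase).
#' @return an [IeegRecording-class] with \code{unit = "amplitude"}.
#' @export
extractHFB <- function(rec, band = c(110, 140), order = 4) {
    if (length(band) != 2L || band[1L] <= 0 || diff(band) <= 0)
        stop("band must be an increasing positive pair")
    if (band[2L] >= rec@fs / 2)
        stop("upper band edge must be below the Nyquist frequency")
    bp <- signal::butter(order, band / (rec@fs / 2), type = "pass")
    out <- rec@data
    for (j in seq_len(ncol(out))) {
        filtered <- signal::filtfilt(bp, rec@data[, j])
        out[, j] <- Mod(analyticSignal(filtered))
    }
    rec@data <- out
    rec@unit <- "amplitude"
    rec
}

#' Cut a recording into per-block epochs
#'
#' Extracts one epoch per retained stimulus block over
#' \code{window} relative to block onset, with \code{margin} seconds of
#' pre-onset samples kept at the front for later baseline statistics.
#' Blocks listed in \code{excluded_blocks} are dropped.
#'
#' @param rec an amplitude [IeegRecording-class] (any unit accepted).
#' @param events validated events data.frame (see [readEvents()]).
#' @param window epoch window relative to onset, seconds.
#' @param margin pre-onset baseline margin, seconds.
#' @param excluded_blocks block indices to drop.
#' @return an [HFBEpochs-class] object at the recording's sampling rate.
#' @export
epochBlocks <- function(rec, events, window = c(0, 30), margin = 0.2,
                        excluded_blocks = numeric()) {
    keep <- !(events$block_index %in% excluded_blocks)
    ev <- events[keep, , drop = FALSE]
    if (!nrow(ev)) stop("no blocks retained after exclusions")
    fs <- rec@fs
    n_time <- round((margin + diff(window)) * fs)
    n_margin <- round(margin * fs)
    out <- array(0, dim = c(nrow(ev), ncol(rec@data), n_time))
    for (b in seq_len(nrow(ev))) {
        start <- round((ev$onset[b] + window[1L]) * fs) - n_margin + 1L
        idx <- start:(start + n_time - 1L)
        if (start < 1L || max(idx) > nrow(rec@data))
            stop(sprintf("block %d [%g s] extends beyond the recording",
                         ev$block_index[b], ev$onset[b]))
        out[b, , ] <- t(rec@data[idx, , drop = FALSE])
    }
    meta <- data.frame(block_index = ev$block_index,
                       condition = ev$condition, onset = ev$onset,
                       stringsAsFactors = FALSE)
    new("HFBEpochs", data = out, fs = fs, blockMeta = meta,
        channels = rec@channels, margin = margin, stage = "amplitude")
}

#' Downsample amplitude epochs
#'
#' Anti-aliased rate conversion of every block/channel trace (zero-phase
#' low-pass at 0.8 x the new Nyquist, then interpolation at the target
#' grid). Plain decimation is never used.
#'
#' @param epochs an [HFBEpochs-class] object.
#' @param target_fs new rate, Hz; must not exceed the current rate.
#' @return the downsampled [HFBEpochs-class].
#' @export
downsampleEpochs <- function(epochs, target_fs = 400) {
    if (target_fs > epochs@fs)
        stop("target_fs must not exceed the current sampling rate")
    if (target_fs == epochs@fs) return(epochs)
    d <- dim(epochs@data)
    n_out <- round(d[3L] / epochs@fs * target_fs)
    out <- array(0, dim = c(d[1L], d[2L], n_out))
    for (b in seq_len(d[1L]))
        for (j in seq_len(d[2L]))
            out[b, j, ] <- resampleSignal(epochs@data[b, j, ], epochs@fs,
                                          target_fs, n_out = n_out)
    # interpolation can very slightly undershoot zero near sharp dips
    out[out < 0] <- 0
    epochs@data <- out
    epochs@fs <- target_fs
    epochs@stage <- "downsampled"
    epochs
}

#' Square-root transform of amplitudes
#'
#' Element-wise square root, applied between downsampling and baseline
#' normalization to stabilize the variance of the amplitude values.
#'
#' @param epochs an [HFBEpochs-class] with non-negative values.
#' @return the transformed [HFBEpochs-class].
#' @export
sqrtTransform <- function(epochs) {
    if (min(epochs@data) < 0)
        stop("negative amplitude before sqrt: upstream processing bug")
    epochs@data <- sqrt(epochs@data)
    epochs@stage <- "sqrt"
    epochs
}

#' Baseline z-score normalization
#'
#' For every block and channel, subtracts the mean and divides by the
#' standard deviation of the pre-onset baseline samples (the margin
#' attached by [epochBlocks()], default -0.2-0 s).
#'
#' @param epochs an [HFBEpochs-class] object.
#' @return the normalized [HFBEpochs-class] (z units).
#' @export
normalizeHFB <- function(epochs) {
    n_margin <- round(epochs@margin * epochs@fs)
    if (n_margin < 2L)
        stop("baseline margin too short for z-scoring")
    d <- dim(epochs@data)
    for (b in seq_len(d[1L])) {
        for (j in seq_len(d[2L])) {
            bl <- epochs@data[b, j, seq_len(n_margin)]
            s <- stats::sd(bl)
            if (s == 0)
                stop(sprintf(
                    "constant baseline in block %d channel %d", b, j))
            epochs@data[b, j, ] <- (epochs@data[b, j, ] - mean(bl)) / s
        }
    }
    epochs@stage <- "normalized"
    epochs
}

#' Flag channels with extreme amplitudes
#'
#' Optional replacement for visual artifact screening: a channel is flagged
#' bad when more than \code{prop} of its samples deviate from the median by
#' more than \code{threshold} robust standard deviations (MAD). Off by
#' default in the pipeline.
#'
#' @param rec an [IeegRecording-class] object.
#' @param threshold robust-SD multiple.
#' @param prop maximal tolerated proportion of extreme samples.
#' @return the recording with updated channel \code{status}.
#' @export
flagBadChannels <- function(rec, threshold = 8, prop = 0.01) {
    for (j in seq_len(ncol(rec@data))) {
        x <- rec@data[, j]
        s <- stats::mad(x)
        if (s == 0) next
        frac <- mean(abs(x - stats::median(x)) > threshold * s)
        if (frac > prop) rec@channels$status[j] <- "bad"
    }
    rec
}

#' Full preprocessing chain
#'
#' Runs notch -> common average reference -> band-pass + analytic amplitude
#' -> epoching -> downsampling -> square root -> baseline z-score, with all
#' constants taken from the configuration.
#'
#' @param rec a raw [IeegRecording-class] object.
#' @param events validated events data.frame.
#' @param config a [PipelineConfig-class] object.
#' @return a normalized [HFBEpochs-class] object.
#' @examples
#' cfg <- pipelineConfig()
#' sub <- simulateSubject(seed = 1, n_blocks = 5, level = "raw",
#'                        n_contacts = 2, config = cfg)
#' ep <- preprocessRecording(sub$recording, sub$events, cfg)
#' @export
preprocessRecording <- function(rec, events, config = pipelineConfig()) {
    rec <- notchFilter(rec, config@line_freq, config@notch_q)
    rec <- commonAverageReference(rec)
    rec <- extractHFB(rec, config@hfb_band, config@filter_order)
    ep <- epochBlocks(rec, events, window = config@epoch_window,
                      margin = -config@baseline_window[1L],
                      excluded_blocks = config@excluded_blocks)
    ep <- downsampleEpochs(ep, config@target_fs)
    ep <- sqrtTransform(ep)
    normalizeHFB(ep)
}
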