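# Emotion-feature handling: aggregation over faces, 2 Hz bin-average
# resampling, lagged design construction, response binning and per-condition
# assembly. Feature and response bins share one half-open window convention
# ([start, end)) so both refer to the same stimulus time.

#' Aggregate per-face scores into per-frame scores
#'
#' When several faces are visible in a frame, each emotion takes the
#' maximum score across faces. Frames with no face become all-zero rows and
#' are flagged.
#'
#' @param scores either a 3-D frames x faces x features array (NA for
#'   absent faces) or a long data.frame with columns \code{time},
#'   \code{face_id} and one column per feature.
#' @param feature_names feature columns expected in the data.frame form.
#' @return frames x features matrix with attribute \code{no_face}, a
#'   logical vector marking frames without any face; data.frame input also
#'   yields attribute \code{time}.
#' @export
aggregateFaces <- function(scores, feature_names = emotionVocabulary()) {
    if (is.array(scores) && length(dim(scores)) == 3L) {
        rng <- range(scores, na.rm = TRUE)
        if (rng[1L] < 0 || rng[2L] > 1)
            stop("scores must lie in [0, 1]")
        out <- apply(scores, c(1L, 3L), function(v)
            if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
        no_face <- apply(is.na(out), 1L, all)
        out[is.na(out)] <- 0
        attr(out, "no_face") <- no_face
        return(out)
    }
    if (!is.data.frame(scores) ||
        !all(c("time", "face_id") %in% names(scores)))
        stop("scores must be a 3-D array or a data.frame with time/face_id")
    miss <- setdiff(feature_names, names(scores))
    if (length(miss))
        stop("missing feature column(s): ", paste(miss, collapse = ", "))
    vals <- as.matrix(scores[feature_names])
    if (any(!is.finite(vals)) || min(vals) < 0 || max(vals) > 1)
        stop("scores must lie in [0, 1]")
    times <- sort(unique(scores$time))
    out <- matrix(0, length(times), length(feature_names),
                  dimnames = list(NULL, feature_names))
    grp <- match(scores$time, times)
    for (k in seq_len(ncol(vals)))
        out[, k] <- vapply(split(vals[, k], grp), max, 0)
    attr(out, "no_face") <- rep(FALSE, length(times))
    attr(out, "time") <- times
    out
}

#' Resample frame-level features to the analysis rate
#'
#' Bin-averages per-frame feature scores into half-open windows of
#' \code{1/target_fs} seconds aligned to each block onset (the same
#' convention as [binResponse()], and inherently anti-aliasing). Empty bins
#' inside a block carry the previous bin's value (leading empty bins carry
#' the first observed value) and are flagged; a block with no frames at all
#' is an error.
#'
#' @param raw data.frame with a \code{time} column (seconds from recording
#'   start) and one column per feature; typically the output of
#'   [aggregateFaces()] joined back to frame times, or a direct feature
#'   table from [readFeatureTable()].
#' @param events validated events data.frame.
#' @param target_fs output rate, Hz.
#' @param feature_names feature columns to use.
#' @param excluded_blocks block indices to drop before resampling.
#' @return a [FeatureTimecourse-class] at \code{target_fs}; attribute
#'   \code{filled} counts carried-forward bins per block.
#' @export
resampleFeatures <- function(raw, events, target_fs = 2,
                             feature_names = emotionVocabulary(),
                             excluded_blocks = numeric()) {
    miss <- setdiff(feature_names, names(raw))
    if (length(miss))
        stop("missing feature column(s): ", paste(miss, collapse = ", "))
    ev <- events[!(events$block_index %in% excluded_blocks), , drop = FALSE]
    if (!nrow(ev)) stop("no blocks retained after exclusions")
    w <- 1 / target_fs
    vals <- as.matrix(raw[feature_names])
    filled <- integer(nrow(ev))
    blocks <- vector("list", nrow(ev))
    for (b in seq_len(nrow(ev))) {
        n_bins <- round(ev$duration[b] * target_fs)
        inb <- raw$time >= ev$onset[b] &
            raw$time < ev$onset[b] + ev$duration[b]
        if (!any(inb))
            stop(sprintf("block %d contains no feature frames",
                         ev$block_index[b]))
        bin <- floor((raw$time[inb] - ev$onset[b]) / w) + 1L
        m <- matrix(NA_real_, n_bins, length(feature_names))
        sub <- vals[inb, , drop = FALSE]
        for (k in seq_along(feature_names))
            m[sort(unique(bin)), k] <-
                vapply(split(sub[, k], bin), mean, 0)
        empty <- is.na(m[, 1L])
        if (any(empty)) {
            filled[b] <- sum(empty)
            first <- which(!empty)[1L]
            if (first > 1L)
                m[seq_len(first - 1L), ] <-
                    m[rep(first, first - 1L), , drop = FALSE]
            for (i in which(is.na(m[, 1L])))
                m[i, ] <- m[i - 1L, ]
        }
        blocks[[b]] <- m
    }
    arr <- array(0, dim = c(nrow(ev), nrow(blocks[[1L]]),
                            length(feature_names)),
                 dimnames = list(NULL, NULL, feature_names))
    for (b in seq_len(nrow(ev))) arr[b, , ] <- blocks[[b]]
    arr[arr < 0] <- 0
    arr[arr > 1] <- 1
    ft <- new("FeatureTimecourse", values = arr, fs = target_fs,
              blockMeta = data.frame(block_index = ev$block_index,
                                     condition = ev$condition,
                                     stringsAsFactors = FALSE))
    attr(ft, "filled") <- filled
    ft
}

#' Build the lagged design matrix
#'
#' Expands each feature into one column per delay: column (feature f, lag
#' tau) at bin t holds feature f at bin t - tau within the same block
#' (the stimulus precedes the response). Bins whose lagged time precedes
#' the block start are zero-padded; blocks never leak into each other.
#' Columns are ordered feature-major, then lag.
#'
#' @param features a [FeatureTimecourse-class] object.
#' @param lags delays in seconds; each must be a multiple of
#'   \code{1/samplingRate(features)}.
#' @return a [LaggedDesign-class] with rows stacked block-major.
#' @export
buildDesignMatrix <- function(features, lags = c(0, 0.5, 1)) {
    fs <- features@fs
    shifts <- lags * fs
    if (any(abs(shifts - round(shifts)) > 1e-9))
        stop("each lag must be a multiple of 1/feature_fs")
    shifts <- as.integer(round(shifts))
    d <- dim(features@values)
    fnames <- dimnames(features@values)[[3L]]
    n_bins <- d[2L]
    X <- lagExpand(features@values, shifts)
    colLabels <- data.frame(
        feature = rep(fnames, each = length(lags)),
        lag = rep(lags, d[3L]), stringsAsFactors = FALSE)
    rowMeta <- data.frame(
        block_index = rep(features@blockMeta$block_index, each = n_bins),
        bin = rep(seq_len(n_bins), d[1L]),
        condition = rep(features@blockMeta$condition, each = n_bins),
        stringsAsFactors = FALSE)
    new("LaggedDesign", X = X, colLabels = colLabels, rowMeta = rowMeta)
}

#' Bin HFB epochs into response rows
#'
#' Averages normalized HFB samples within successive half-open windows of
#' \code{bin_width} seconds over the post-onset epoch (the baseline margin
#' is excluded). With 30 s blocks at 400 Hz and 0.5 s bins this yields 60
#' bins of 200 samples per block.
#'
#' @param epochs a normalized [HFBEpochs-class] object.
#' @param bin_width bin width in seconds; \code{bin_width * fs} must be an
#'   integer.
#' @return a [BinnedResponse-class]: rows are bins stacked block-major,
#'   columns are contacts (named from the channel table).
#' @export
binResponse <- function(epochs, bin_width = 0.5) {
    spb <- bin_width * epochs@fs
    if (abs(spb - round(spb)) > 1e-9)
        stop("bin_width * fs must be an integer number of samples")
    spb <- as.integer(round(spb))
    n_margin <- round(epochs@margin * epochs@fs)
    d <- dim(epochs@data)
    n_post <- d[3L] - n_margin
    n_bins <- n_post %/% spb
    rows <- vector("list", d[1L])
    for (b in seq_len(d[1L])) {
        seg <- epochs@data[b, , n_margin + seq_len(n_bins * spb),
                           drop = FALSE]
        m <- matrix(0, n_bins, d[2L])
        for (j in seq_len(d[2L]))
            m[, j] <- colMeans(matrix(seg[1L, j, ], nrow = spb))
        rows[[b]] <- m
    }
    y <- do.call(rbind, rows)
    colnames(y) <- if (nrow(epochs@channels)) epochs@channels$name else NULL
    rowMeta <- data.frame(
        block_index = rep(epochs@blockMeta$block_index, each = n_bins),
        bin = rep(seq_len(n_bins), d[1L]),
        condition = rep(epochs@blockMeta$condition, each = n_bins),
        stringsAsFactors = FALSE)
    new("BinnedResponse", y = y, rowMeta = rowMeta)
}

#' Assemble one condition's design/response pair
#'
#' Subsets a lagged design and a binned response to the blocks of one
#' condition, keeping stimulus order, and verifies that the two refer to
#' identical (block, bin) rows.
#'
#' @param design a [LaggedDesign-class] object.
#' @param response a [BinnedResponse-class] object.
#' @param condition \code{"speech"} or \code{"music"}.
#' @return list with elements \code{design} and \code{response}, both
#'   subset to the condition.
#' @export
assembleCondition <- function(design, response, condition) {
    di <- design@rowMeta$condition == condition
    ri <- response@rowMeta$condition == condition
    if (!any(di) || !any(ri))
        stop("no retained blocks for condition: ", condition)
    dm <- design@rowMeta[di, c("block_index", "bin")]
    rm_ <- response@rowMeta[ri, c("block_index", "bin")]
    if (!identical(unname(as.matrix(dm)), unname(as.matrix(rm_))))
        stop("design and response rows do not align for ", condition)
    list(design = new("LaggedDesign", X = design@X[di, , drop = FALSE],
                      colLabels = design@colLabels,
                      rowMeta = design@rowMeta[di, , drop = FALSE]),
         response = new("BinnedResponse",
                        y = response@y[ri, , drop = FALSE],
                        rowMeta = response@rowMeta[ri, , drop = FALSE]))
}
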