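#' @import methods
NULL

#' IeegRecording: multichannel intracranial time series
#'
#' Container for a continuous multichannel recording: a samples x channels
#' numeric matrix, its sampling rate, a channel table (name, region,
#' hemisphere, status) and optional subject metadata. The same class carries
#' both raw voltage traces and derived amplitude traces; the \code{unit} slot
#' records which.
#'
#' @slot data numeric matrix, samples x channels (arbitrary linear units).
#' @slot fs sampling rate in Hz.
#' @slot channels data.frame with columns \code{name}, \code{region}
#'   (\code{"DLPFC"}, \code{"pSTC"} or \code{"other"}), \code{hemisphere}
#'   (\code{"L"}/\code{"R"}) and \code{status} (\code{"good"}/\code{"bad"}).
#' @slot subject list with elements \code{id}, \code{age}, \code{group} and
#'   optionally \code{sex}; may be empty.
#' @slot unit character, \code{"signal"} for raw traces or
#'   \code{"amplitude"} after envelope extraction.
#'
#' @seealso [readRecording()], [notchFilter()], [extractHFB()]
#' @export
setClass("IeegRecording",
    representation(data = "matrix", fs = "numeric", channels = "data.frame",
                   subject = "list", unit = "character"),
    prototype(subject = list(), unit = "signal"))

setValidity("IeegRecording", function(object) {
    msg <- character()
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
        msg <- c(msg, "fs must be a single positive number")
    ch <- object@channels
    need <- c("name", "region", "hemisphere", "status")
    if (!all(need %in% names(ch)))
        msg <- c(msg, paste("channel table must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (nrow(ch) != ncol(object@data))
            msg <- c(msg, "channel table rows must match data columns")
        if (anyDuplicated(ch$name))
            msg <- c(msg, "channel names must be unique")
        if (!all(ch$region %in% c("DLPFC", "pSTC", "other")))
            msg <- c(msg, "region must be one of DLPFC, pSTC, other")
        if (!all(ch$status %in% c("good", "bad")))
            msg <- c(msg, "status must be good or bad")
        good <- ch$status == "good"
        if (any(good) && ncol(object@data) &&
            !all(is.finite(object@data[, good])))
            msg <- c(msg, "good channels must contain only finite values")
    }
    if (!object@unit %in% c("signal", "amplitude"))
        msg <- c(msg, "unit must be 'signal' or 'amplitude'")
    if (length(msg)) msg else TRUE
})

#' HFBEpochs: per-block high-frequency-band amplitude epochs
#'
#' Blocks x channels x time array of high-frequency-band amplitude, carrying
#' per-block condition metadata and a short pre-onset margin used only for
#' baseline statistics. The \code{stage} slot tracks progress through the
#' amplitude -> downsample -> sqrt -> z-score chain.
#'
#' @slot data numeric array, blocks x channels x time.
#' @slot fs sampling rate of the time axis, Hz.
#' @slot blockMeta data.frame with columns \code{block_index},
#'   \code{condition} and \code{onset} (seconds), one row per block.
#' @slot channels data.frame, the channel table of the source recording.
#' @slot margin seconds of pre-onset samples kept at the start of the time
#'   axis (baseline window).
#' @slot stage character, one of \code{"amplitude"}, \code{"downsampled"},
#'   \code{"sqrt"}, \code{"normalized"}.
#' @export
setClass("HFBEpochs",
    representation(data = "array", fs = "numeric", blockMeta = "data.frame",
                   channels = "data.frame", margin = "numeric",
                   stage = "character"),
    prototype(margin = 0.2, stage = "amplitude"))

setValidity("HFBEpochs", function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 3L)
        msg <- c(msg, "data must be a 3-D blocks x channels x time array")
    else {
        if (d[1L] != nrow(object@blockMeta))
            msg <- c(msg, "first dimension must match blockMeta rows")
        if (nrow(object@channels) && d[2L] != nrow(object@channels))
            msg <- c(msg, "second dimension must match channel table rows")
    }
    if (!all(c("block_index", "condition", "onset") %in%
             names(object@blockMeta)))
        msg <- c(msg, "blockMeta needs block_index, condition, onset")
    else if (!all(object@blockMeta$condition %in% c("speech", "music")))
        msg <- c(msg, "condition must be speech or music")
    if (object@margin < 0)
        msg <- c(msg, "margin must be non-negative")
    if (!object@stage %in% c("amplitude", "downsampled", "sqrt", "normalized"))
        msg <- c(msg, "unknown stage")
    if (object@stage %in% c("amplitude", "downsampled") &&
        length(object@data) && min(object@data) < 0)
        msg <- c(msg, "amplitudes must be non-negative before sqrt/z-score")
    if (length(msg)) msg else TRUE
})

#' FeatureTimecourse: per-block emotion feature scores
#'
#' Blocks x time x features array of bounded emotion scores sampled at a
#' fixed rate (2 Hz by default), with feature names on the third dimension.
#'
#' @slot values numeric array, blocks x time x features, each value in
#'   \eqn{[0, 1]}.
#' @slot fs feature sampling rate, Hz.
#' @slot blockMeta data.frame with columns \code{block_index} and
#'   \code{condition}.
#' @export
setClass("FeatureTimecourse",
    representation(values = "array", fs = "numeric",
                   blockMeta = "data.frame"))

setValidity("FeatureTimecourse", function(object) {
    msg <- character()
    d <- dim(object@values)
    if (length(d) != 3L)
        msg <- c(msg, "values must be a 3-D blocks x time x features array")
    else {
        if (d[1L] != nrow(object@blockMeta))
            msg <- c(msg, "first dimension must match blockMeta rows")
        if (is.null(dimnames(object@values)[[3L]]))
            msg <- c(msg, "feature names required on the third dimension")
    }
    if (length(object@values) &&
        (min(object@values) < 0 || max(object@values) > 1))
        msg <- c(msg, "feature values must lie in [0, 1]")
    if (!all(c("block_index", "condition") %in% names(object@blockMeta)))
        msg <- c(msg, "blockMeta needs block_index and condition")
    if (length(object@fs) != 1L || object@fs <= 0)
        msg <- c(msg, "fs must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' LaggedDesign: time-lagged feature design matrix
#'
#' Rows are stimulus time bins (optionally replicated per contact after
#' concatenation), columns are (feature, lag) pairs ordered feature-major.
#'
#' @slot X numeric design matrix.
#' @slot colLabels data.frame with columns \code{feature} and \code{lag}
#'   (seconds), one row per column of \code{X}.
#' @slot rowMeta data.frame with columns \code{block_index}, \code{bin},
#'   \code{condition} and, after contact concatenation, \code{contact}.
#' @export
setClass("LaggedDesign",
    representation(X = "matrix", colLabels = "data.frame",
                   rowMeta = "data.frame"))

setValidity("LaggedDesign", function(object) {
    msg <- character()
    if (nrow(object@X) != nrow(object@rowMeta))
        msg <- c(msg, "rowMeta rows must match X rows")
    if (ncol(object@X) != nrow(object@colLabels))
        msg <- c(msg, "colLabels rows must match X columns")
    if (!all(c("feature", "lag") %in% names(object@colLabels)))
        msg <- c(msg, "colLabels needs feature and lag")
    if (!all(c("block_index", "bin") %in% names(object@rowMeta)))
        msg <- c(msg, "rowMeta needs block_index and bin")
    if (length(msg)) msg else TRUE
})

#' BinnedResponse: bin-averaged HFB response per contact
#'
#' Rows are stimulus time bins stacked block-major (matching a
#' [LaggedDesign]); columns are recording contacts.
#'
#' @slot y numeric matrix, bins x contacts, z-scored units.
#' @slot rowMeta data.frame with columns \code{block_index}, \code{bin},
#'   \code{condition}.
#' @export
setClass("BinnedResponse",
    representation(y = "matrix", rowMeta = "data.frame"))

setValidity("BinnedResponse", function(object) {
    msg <- character()
    if (nrow(object@y) != nrow(object@rowMeta))
        msg <- c(msg, "rowMeta rows must match y rows")
    if (!all(c("block_index", "bin", "condition") %in% names(object@rowMeta)))
        msg <- c(msg, "rowMeta needs block_index, bin, condition")
    if (length(object@y) && !all(is.finite(object@y)))
        msg <- c(msg, "responses must be finite")
    if (length(msg)) msg else TRUE
})

#' EncodingFit: cross-validated ridge encoding model
#'
#' One fitted encoding model for a (subject, region, condition) cell: the
#' shared ridge coefficient, per-fold weight vectors and held-out Pearson
#' accuracies, and their mean.
#'
#' @slot subject subject identifier.
#' @slot region region label (\code{"DLPFC"} or \code{"pSTC"}).
#' @slot condition \code{"speech"} or \code{"music"}.
#' @slot alpha ridge regularization coefficient used.
#' @slot weights matrix, folds x predictors (one row per fold).
#' @slot intercepts numeric, one unpenalized intercept per fold.
#' @slot foldR numeric, held-out Pearson r per fold (may contain NaN for
#'   degenerate folds).
#' @slot meanR mean of the finite per-fold r values.
#' @slot nRows number of stacked rows fitted.
#' @slot nContacts number of contacts concatenated.
#' @slot colLabels data.frame of (feature, lag) labels for weight columns.
#' @export
setClass("EncodingFit",
    representation(subject = "character", region = "character",
                   condition = "character", alpha = "numeric",
                   weights = "matrix", intercepts = "numeric",
                   foldR = "numeric", meanR = "numeric", nRows = "numeric",
                   nContacts = "numeric", colLabels = "data.frame"))

setValidity("EncodingFit", function(object) {
    msg <- character()
    if (nrow(object@weights) != length(object@foldR))
        msg <- c(msg, "one weight row per fold required")
    if (length(object@intercepts) != length(object@foldR))
        msg <- c(msg, "one intercept per fold required")
    if (is.finite(object@meanR) &&
        (object@meanR < -1 - 1e-12 || object@meanR > 1 + 1e-12))
        msg <- c(msg, "meanR must lie in [-1, 1]")
    if (nrow(object@colLabels) &&
        nrow(object@colLabels) != ncol(object@weights))
        msg <- c(msg, "colLabels must match weight columns")
    if (length(msg)) msg else TRUE
})

#' PermutationResult: temporal-shuffle null for one encoding fit
#'
#' @slot observed observed mean held-out Pearson r.
#' @slot nullValues mean r values obtained after shuffling the feature time
#'   courses in time.
#' @slot p two-tailed Monte-Carlo p-value (add-one corrected, so always in
#'   \eqn{(0, 1]} and at least \eqn{1/(n_{perm}+1)}).
#' @slot nPerm number of permutations.
#' @slot seed RNG seed used.
#' @export
setClass("PermutationResult",
    representation(observed = "numeric", nullValues = "numeric",
                   p = "numeric", nPerm = "numeric", seed = "numeric"))

setValidity("PermutationResult", function(object) {
    msg <- character()
    if (length(object@nullValues) != object@nPerm)
        msg <- c(msg, "nullValues length must equal nPerm")
    if (object@p <= 0 || object@p > 1)
        msg <- c(msg, "p must lie in (0, 1]")
    if (object@p < 1 / (object@nPerm + 1) - 1e-12)
        msg <- c(msg, "p cannot be smaller than 1/(nPerm + 1)")
    if (length(msg)) msg else TRUE
})
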