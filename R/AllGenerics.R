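#' @include AllClasses.R config.R
NULL

#' Sampling rate of a time-series container
#' @param x an [IeegRecording-class], [HFBEpochs-class] or
#'   [FeatureTimecourse-class] object.
#' @return sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Channel metadata table
#' @param x an object carrying a channel table.
#' @return data.frame with columns name, region, hemisphere, status.
#' @export
setGeneric("channelInfo", function(x) standardGeneric("channelInfo"))

#' Per-block metadata
#' @param x an [HFBEpochs-class] or [FeatureTimecourse-class] object.
#' @return data.frame with one row per block.
#' @export
setGeneric("blockInfo", function(x) standardGeneric("blockInfo"))

#' Emotion feature names
#' @param x a [FeatureTimecourse-class], [LaggedDesign-class] or
#'   [PipelineConfig-class] object.
#' @return character vector of feature names.
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' Mean held-out prediction accuracy
#' @param x an [EncodingFit-class] object.
#' @return mean across folds of the held-out Pearson r.
#' @export
setGeneric("meanR", function(x) standardGeneric("meanR"))

#' Per-fold held-out prediction accuracy
#' @param x an [EncodingFit-class] object.
#' @return numeric vector, one Pearson r per fold.
#' @export
setGeneric("foldR", function(x) standardGeneric("foldR"))

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "IeegRecording", function(x) x@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "HFBEpochs", function(x) x@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "FeatureTimecourse", function(x) x@fs)

#' @rdname channelInfo
#' @export
setMethod("channelInfo", "IeegRecording", function(x) x@channels)
#' @rdname channelInfo
#' @export
setMethod("channelInfo", "HFBEpochs", function(x) x@channels)

#' @rdname blockInfo
#' @export
setMethod("blockInfo", "HFBEpochs", function(x) x@blockMeta)
#' @rdname blockInfo
#' @export
setMethod("blockInfo", "FeatureTimecourse", function(x) x@blockMeta)

#' @rdname featureNames
#' @export
setMethod("featureNames", "FeatureTimecourse",
          function(x) dimnames(x@values)[[3L]])
#' @rdname featureNames
#' @export
setMethod("featureNames", "PipelineConfig", function(x) x@feature_names)
#' @rdname featureNames
#' @export
setMethod("featureNames", "LaggedDesign",
          function(x) unique(x@colLabels$feature))

#' @rdname meanR
#' @export
setMethod("meanR", "EncodingFit", function(x) x@meanR)
#' @rdname foldR
#' @export
setMethod("foldR", "EncodingFit", function(x) x@foldR)

#' Fold-averaged encoding weights
#'
#' @param object an [EncodingFit-class] object.
#' @param ... unused.
#' @return named numeric vector: the mean over folds of each (feature, lag)
#'   weight, names \code{"<feature>.lag<seconds>"}.
#' @export
setMethod("coef", "EncodingFit", function(object, ...) {
    w <- colMeans(object@weights)
    if (nrow(object@colLabels))
        names(w) <- paste0(object@colLabels$feature, ".lag",
                           object@colLabels$lag)
    w
})

setMethod("show", "IeegRecording", function(object) {
    cat(sprintf("IeegRecording: %d samples x %d channels at %g Hz (%s)\n",
                nrow(object@data), ncol(object@data), object@fs,
                object@unit))
    if (length(object@subject))
        cat(sprintf("  subject: %s\n",
                    paste(unlist(object@subject), collapse = " / ")))
    if (nrow(object@channels)) {
        tab <- table(object@channels$region)
        cat("  regions:", paste(names(tab), tab, sep = "=", collapse = ", "),
            "\n")
        nb <- sum(object@channels$status == "bad")
        if (nb) cat("  bad channels:", nb, "\n")
    }
    invisible(NULL)
})

setMethod("show", "HFBEpochs", function(object) {
    d <- dim(object@data)
    cat(sprintf(
        "HFBEpochs: %d blocks x %d channels x %d samples at %g Hz [%s]\n",
        d[1L], d[2L], d[3L], object@fs, object@stage))
    cat("  conditions:",
        paste(object@blockMeta$condition, collapse = " "), "\n")
    invisible(NULL)
})

setMethod("show", "FeatureTimecourse", function(object) {
    d <- dim(object@values)
    cat(sprintf(
        "FeatureTimecourse: %d blocks x %d samples x %d features at %g Hz\n",
        d[1L], d[2L], d[3L], object@fs))
    invisible(NULL)
})

setMethod("show", "LaggedDesign", function(object) {
    cat(sprintf("LaggedDesign: %d rows x %d columns (%d features x %d lags)\n",
                nrow(object@X), ncol(object@X),
                length(unique(object@colLabels$feature)),
                length(unique(object@colLabels$lag))))
    invisible(NULL)
})

setMethod("show", "BinnedResponse", function(object) {
    cat(sprintf("BinnedResponse: %d bins x %d contacts\n",
                nrow(object@y), ncol(object@y)))
    invisible(NULL)
})

setMethod("show", "EncodingFit", function(object) {
    cat(sprintf("EncodingFit: %s / %s / %s\n", object@subject,
                object@region, object@condition))
    cat(sprintf("  alpha = %.4g, mean held-out r = %.4f (folds: %s)\n",
                object@alpha, object@meanR,
                paste(sprintf("%.3f", object@foldR), collapse = " ")))
    cat(sprintf("  %d rows, %d contacts, %d predictors\n", object@nRows,
                object@nContacts, ncol(object@weights)))
    invisible(NULL)
})

setMethod("show", "PermutationResult", function(object) {
    cat(sprintf(
        "PermutationResult: observed r = %.4f, p = %.4g (%d permutations)\n",
        object@observed, object@p, object@nPerm))
    invisible(NULL)
})

setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig:\n")
    cat(sprintf("  notch %g Hz (Q=%g); band %g-%g Hz order %d; epochs %g-%g s\n",
                object@line_freq, object@notch_q, object@hfb_band[1L],
                object@hfb_band[2L], object@filter_order,
                object@epoch_window[1L], object@epoch_window[2L]))
    cat(sprintf("  baseline %g-%g s; %g Hz amplitude; %g Hz features; %g s bins\n",
                object@baseline_window[1L], object@baseline_window[2L],
                object@target_fs, object@feature_fs, object@bin_width))
    cat(sprintf("  lags: %s s; %d alphas in [%g, %g]; %d folds; %d perms\n",
                paste(object@lags, collapse = ", "),
                length(object@alpha_grid), min(object@alpha_grid),
                max(object@alpha_grid), object@n_folds, object@n_perm))
    cat(sprintf("  %d features; excluded blocks: %s; min contacts: %d\n",
                length(object@feature_names),
                paste(object@excluded_blocks, collapse = ", "),
                object@min_contacts))
    invisible(NULL)
})
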