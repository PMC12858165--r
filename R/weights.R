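# Weight analysis: absolute-weight summaries per feature, complex/basic
# emotion group means, and cross-subject correlation with age.

#' Summarize encoding weights per feature
#'
#' Reduces a fit's folds x (features x lags) weight matrix to one
#' non-negative value per feature: by default the mean of the absolute
#' weights over all lags and folds (the absolute value deliberately ignores
#' whether a feature maps to an increase or decrease of the response).
#' Group means are computed over the configured complex and basic emotion
#' name lists.
#'
#' @param fit an [EncodingFit-class] with (feature, lag) column labels.
#' @param complex_group,basic_group feature-name groups to average.
#' @param reduce \code{"mean"} (default) or \code{"max"} over lags x folds.
#' @return list with \code{per_feature} (named non-negative vector),
#'   \code{complex_mean}, \code{basic_mean} and the fit's identifiers.
#' @export
summarizeWeights <- function(fit,
                             complex_group = c("guilt", "embarrassment",
                                               "pride", "envy"),
                             basic_group = c("joy", "sadness", "fear",
                                             "anger", "disgust",
                                             "surprise"),
                             reduce = c("mean", "max")) {
    reduce <- match.arg(reduce)
    if (!nrow(fit@colLabels))
        stop("fit carries no (feature, lag) column labels")
    if (ncol(fit@weights) != nrow(fit@colLabels))
        stop("weight columns do not match column labels")
    aw <- abs(fit@weights)                   # folds x columns
    feats <- unique(fit@colLabels$feature)
    per_feature <- vapply(feats, function(f) {
        cols <- fit@colLabels$feature == f
        v <- aw[, cols, drop = FALSE]
        if (reduce == "mean") mean(v) else max(v)
    }, 0)
    miss <- setdiff(c(complex_group, basic_group), feats)
    if (length(miss))
        stop("group feature(s) absent from fit: ",
             paste(miss, collapse = ", "))
    list(subject = fit@subject, region = fit@region,
         condition = fit@condition, per_feature = per_feature,
         complex_mean = mean(per_feature[complex_group]),
         basic_mean = mean(per_feature[basic_group]))
}

#' Keep subjects whose prediction is significant
#'
#' @param p_values named numeric vector of permutation p-values per
#'   subject.
#' @param threshold significance threshold.
#' @return character vector of retained subject ids (empty input gives an
#'   empty result).
#' @export
filterIncluded <- function(p_values, threshold = 0.05) {
    as.character(names(p_values)[p_values < threshold])
}

#' Tabulate weight summaries across subjects
#'
#' @param summaries list of [summarizeWeights()] results.
#' @param subjects optional data.frame with \code{id}, \code{age},
#'   \code{group} to join.
#' @return data.frame: subject, region, condition, one column per feature,
#'   complex_mean, basic_mean, and (if joined) age and group.
#' @export
weightTable <- function(summaries, subjects = NULL) {
    if (!length(summaries)) return(data.frame())
    feats <- names(summaries[[1L]]$per_feature)
    tab <- do.call(rbind, lapply(summaries, function(s) {
        row <- data.frame(subject = s$subject, region = s$region,
                          condition = s$condition,
                          stringsAsFactors = FALSE)
        row[feats] <- as.list(s$per_feature[feats])
        row$complex_mean <- s$complex_mean
        row$basic_mean <- s$basic_mean
        row
    }))
    if (!is.null(subjects)) {
        tab$age <- subjects$age[match(tab$subject, subjects$id)]
        tab$group <- subjects$group[match(tab$subject, subjects$id)]
    }
    rownames(tab) <- NULL
    tab
}

#' Correlate per-feature weights with age
#'
#' Pearson correlation (two-sided, uncorrected p) between each feature's
#' absolute weight and subject age, plus the complex/basic group means.
#' Features are returned ranked by r, largest first; ties break by feature
#' name. An optional Benjamini-Hochberg column is provided for convenience
#' but the primary p-values are uncorrected.
#'
#' @param weight_table data.frame from [weightTable()] including an
#'   \code{age} column, one row per included subject.
#' @param features feature columns to correlate (default: every column of
#'   the default vocabulary present in the table).
#' @return list with \code{per_feature} (data.frame feature, r, p, p_adj,
#'   rank) and \code{groups} (data.frame for complex_mean/basic_mean).
#' @export
correlateWithAge <- function(weight_table,
                             features = intersect(emotionVocabulary(),
                                                  names(weight_table))) {
    n <- nrow(weight_table)
    if (n < 3L) stop("need at least 3 subjects")
    age <- weight_table$age
    if (is.null(age) || stats::sd(age) == 0)
        stop("zero variance (or missing) ages")
    corOne <- function(w) {
        if (stats::sd(w) == 0) stop("zero variance in weights")
        ct <- stats::cor.test(w, age, method = "pearson")
        c(r = unname(ct$estimate), p = ct$p.value)
    }
    per <- t(vapply(features, function(f) corOne(weight_table[[f]]),
                    c(r = 0, p = 0)))
    ord <- order(-per[, "r"], features)
    per_feature <- data.frame(feature = features[ord],
                              r = per[ord, "r"], p = per[ord, "p"],
                              p_adj = stats::p.adjust(per[, "p"],
                                                      "BH")[ord],
                              rank = seq_along(features),
                              stringsAsFactors = FALSE)
    rownames(per_feature) <- NULL
    groups <- do.call(rbind, lapply(
        intersect(c("complex_mean", "basic_mean"), names(weight_table)),
        function(g) {
            v <- corOne(weight_table[[g]])
            data.frame(group = g, r = v[["r"]], p = v[["p"]], n = n,
                       stringsAsFactors = FALSE)
        }))
    list(per_feature = per_feature, groups = groups)
}
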