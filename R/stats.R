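# Inference on prediction accuracies: the temporal-shuffle permutation test
# and the parametric group-level contrasts.

# Lag-expand a blocks x time x features array into a plain design matrix
# (rows block-major). Shared by buildDesignMatrix and the permutation loop.
lagExpand <- function(values, shifts) {
    d <- dim(values)
    n_bins <- d[2L]
    X <- matrix(0, d[1L] * n_bins, d[3L] * length(shifts))
    for (b in seq_len(d[1L])) {
        rows <- (b - 1L) * n_bins + seq_len(n_bins)
        col <- 0L
        for (f in seq_len(d[3L])) {
            xf <- values[b, , f]
            for (s in shifts) {
                col <- col + 1L
                if (s == 0L) X[rows, col] <- xf
                else X[rows[-seq_len(s)], col] <- xf[seq_len(n_bins - s)]
            }
        }
    }
    X
}

#' Temporal-shuffle permutation test of an encoding fit
#'
#' Destroys the temporal alignment between features and response while
#' preserving everything else: all feature rows of the condition's 2 Hz
#' time course are permuted jointly (the 48 features move together, so
#' their instantaneous covariance survives), the lagged design is rebuilt,
#' and the cross-validated fit is rerun at the same ridge coefficient and
#' fold partition. The two-tailed p-value is the add-one-corrected
#' proportion of null accuracies at least as far from the null median as
#' the observed one, so \eqn{p \in (0, 1]} and \eqn{p \ge 1/(n_{perm}+1)}.
#'
#' @param features a [FeatureTimecourse-class] covering (at least) the
#'   condition's blocks.
#' @param response the matching [BinnedResponse-class] (all blocks).
#' @param condition \code{"speech"} or \code{"music"}.
#' @param alpha ridge coefficient (the shared value; it is not re-selected
#'   inside permutations).
#' @param lags delays in seconds.
#' @param n_folds cross-validation folds.
#' @param n_perm number of permutations, \eqn{\ge 1}.
#' @param seed RNG seed.
#' @param contacts contact columns to use (default all).
#' @param scheme fold scheme.
#' @param perm_scheme \code{"shuffle"} (joint row permutation) or
#'   \code{"circular"} (random circular shift of the condition rows).
#' @return a [PermutationResult-class] object.
#' @export
permutationTest <- function(features, response, condition, alpha,
                            lags = c(0, 0.5, 1), n_folds = 5,
                            n_perm = 1000, seed = 1, contacts = NULL,
                            scheme = "contiguous",
                            perm_scheme = "shuffle") {
    if (n_perm < 1) stop("n_perm must be >= 1")
    bsel <- features@blockMeta$condition == condition
    if (!any(bsel)) stop("no feature blocks for condition: ", condition)
    vals <- features@values[bsel, , , drop = FALSE]
    d <- dim(vals)
    shifts <- as.integer(round(lags * features@fs))
    rsel <- response@rowMeta$condition == condition
    Y <- response@y[rsel, , drop = FALSE]
    if (nrow(Y) != d[1L] * d[2L])
        stop("feature and response rows do not align for ", condition)
    if (!is.null(contacts)) Y <- Y[, contacts, drop = FALSE]
    nc <- ncol(Y)
    n <- nrow(Y)
    base <- rep(seq_len(n), nc)
    y <- as.numeric(Y)
    folds <- makeFolds(base, n_folds, scheme)
    tile <- rep(seq_len(n), nc)
    meanCvR <- function(X) {
        r <- cvCurve(X[tile, , drop = FALSE], y, alpha, folds)
        mean(r[is.finite(r)])
    }
    observed <- meanCvR(lagExpand(vals, shifts))
    # feature rows pooled across the condition's blocks, block-major
    stacked <- matrix(aperm(vals, c(2L, 1L, 3L)), n, d[3L])
    set.seed(seed)
    nulls <- numeric(n_perm)
    perm_vals <- vals
    for (i in seq_len(n_perm)) {
        idx <- if (perm_scheme == "circular") {
            k <- sample.int(n - 1L, 1L)
            c((k + 1L):n, seq_len(k))
        } else sample.int(n)
        sp <- stacked[idx, , drop = FALSE]
        for (b in seq_len(d[1L]))
            perm_vals[b, , ] <- sp[(b - 1L) * d[2L] + seq_len(d[2L]), ]
        nulls[i] <- meanCvR(lagExpand(perm_vals, shifts))
    }
    med <- stats::median(nulls)
    p <- (1 + sum(abs(nulls - med) >= abs(observed - med))) / (n_perm + 1)
    new("PermutationResult", observed = observed, nullValues = nulls,
        p = p, nPerm = n_perm, seed = seed)
}

groupStat <- function(test, statistic, df, p, n1, n2 = NA_integer_) {
    # all three conventions (one-sample, paired, pooled unpaired) have
    # integer degrees of freedom
    data.frame(test = test, statistic = statistic,
               df = as.integer(round(df)), p = p, n1 = n1, n2 = n2,
               stringsAsFactors = FALSE)
}

#' One-sample t-test on prediction accuracies
#'
#' Two-sided test of the mean against \code{popmean} with \eqn{df = n - 1}.
#' A zero-variance sample is an error unless its mean equals
#' \code{popmean}, in which case the statistic is 0 and p is 1.
#'
#' @param x numeric vector (per-subject mean accuracies), length >= 2.
#' @param popmean null value.
#' @return one-row data.frame: test, statistic, df, p, n1, n2.
#' @export
oneSampleT <- function(x, popmean = 0) {
    if (length(x) < 2L) stop("need at least 2 values")
    if (stats::sd(x) == 0) {
        if (isTRUE(all.equal(mean(x), popmean)))
            return(groupStat("one_sample_t", 0, length(x) - 1L, 1,
                             length(x)))
        stop("zero variance")
    }
    tt <- stats::t.test(x, mu = popmean)
    groupStat("one_sample_t", unname(tt$statistic),
              unname(tt$parameter), tt$p.value, length(x))
}

#' Paired t-test
#'
#' One-sample t-test on the paired differences, \eqn{df = n - 1}.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return one-row data.frame as in [oneSampleT()].
#' @export
pairedT <- function(a, b) {
    if (length(a) != length(b)) stop("paired samples must have equal length")
    out <- oneSampleT(a - b, popmean = 0)
    out$test <- "paired_t"
    out$n2 <- length(b)
    out
}

#' Unpaired two-sample t-test (pooled variance)
#'
#' Equal-variance two-sample t-test with \eqn{df = n_1 + n_2 - 2} (the
#' convention matching the degrees of freedom reported for the group
#' contrasts, e.g. df = 19 for groups of 8 and 13).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return one-row data.frame as in [oneSampleT()].
#' @export
unpairedT <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least 2 values")
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (isTRUE(all.equal(mean(a), mean(b))))
            return(groupStat("unpaired_t", 0,
                             length(a) + length(b) - 2L, 1,
                             length(a), length(b)))
        stop("zero pooled variance")
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    groupStat("unpaired_t", unname(tt$statistic), unname(tt$parameter),
              tt$p.value, length(a), length(b))
}

#' Voice effect: speech-minus-music accuracy contrast
#'
#' For every subject with both conditions fitted in the given region,
#' computes \eqn{\Delta r = r_{speech} - r_{music}}; when group labels are
#' supplied, the two groups' \eqn{\Delta r} values are compared with the
#' pooled-variance unpaired t-test.
#'
#' @param fits list of [EncodingFit-class] objects.
#' @param region region to restrict to (default: all regions present, one
#'   pair per subject x region).
#' @param groups optional named character vector mapping subject id to
#'   group label (exactly two groups for the contrast).
#' @return list with \code{deltas} (data.frame subject, region, r_speech,
#'   r_music, delta, group) and \code{contrast} (unpaired t data.frame, or
#'   NULL when no groups are given).
#' @export
voiceEffect <- function(fits, region = NULL, groups = NULL) {
    keys <- data.frame(
        subject = vapply(fits, function(f) f@subject, ""),
        region = vapply(fits, function(f) f@region, ""),
        condition = vapply(fits, function(f) f@condition, ""),
        r = vapply(fits, function(f) f@meanR, 0),
        stringsAsFactors = FALSE)
    if (!is.null(region)) keys <- keys[keys$region == region, ]
    sp <- keys[keys$condition == "speech", ]
    mu <- keys[keys$condition == "music", ]
    m <- merge(sp, mu, by = c("subject", "region"),
               suffixes = c("_speech", "_music"))
    if (!nrow(m)) stop("no subject has both conditions fitted")
    deltas <- data.frame(subject = m$subject, region = m$region,
                         r_speech = m$r_speech, r_music = m$r_music,
                         delta = m$r_speech - m$r_music,
                         stringsAsFactors = FALSE)
    contrast <- NULL
    if (!is.null(groups)) {
        deltas$group <- unname(groups[deltas$subject])
        gl <- sort(unique(deltas$group))
        if (length(gl) == 2L) {
            contrast <- unpairedT(deltas$delta[deltas$group == gl[1L]],
                                  deltas$delta[deltas$group == gl[2L]])
            contrast$groups <- paste(gl, collapse = " vs ")
        }
    }
    list(deltas = deltas, contrast = contrast)
}
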