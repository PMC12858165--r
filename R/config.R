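#' @include AllClasses.R
NULL

#' The default 48-expression emotion vocabulary
#'
#' Names for the 48 continuous facial-expression features the pipeline
#' expects, in the style of modern facial-expression inference services.
#' The list is a configurable default, not a contract: every analysis is
#' name-driven, so any 48 (or other number of) unique names can be supplied
#' through [pipelineConfig()]. The default contains the six basic emotions
#' (joy, sadness, fear, anger, disgust, surprise) and the self-conscious
#' "complex" emotions (guilt, embarrassment, pride, envy, plus interest)
#' used by the weight analysis.
#'
#' @return character vector of 48 unique feature names.
#' @examples
#' length(emotionVocabulary())
#' @export
emotionVocabulary <- function() {
    c("admiration", "adoration", "aesthetic_appreciation", "amusement",
      "anger", "anxiety", "awe", "awkwardness", "boredom", "calmness",
      "concentration", "confusion", "contemplation", "contempt",
      "contentment", "craving", "desire", "determination", "disappointment",
      "disgust", "distress", "doubt", "ecstasy", "embarrassment",
      "empathic_pain", "entrancement", "envy", "excitement", "fear",
      "gratitude", "guilt", "horror", "interest", "joy", "love",
      "nostalgia", "pain", "pride", "realization", "relief", "romance",
      "sadness", "satisfaction", "shame", "surprise", "sympathy",
      "tiredness", "triumph")
}

#' PipelineConfig: all numeric constants of the analysis in one object
#'
#' @slot line_freq power-line frequency removed by the notch filter, Hz.
#' @slot hfb_band high-frequency-band edges, Hz.
#' @slot filter_order Butterworth band-pass order.
#' @slot epoch_window block window relative to onset, seconds.
#' @slot baseline_window baseline window relative to onset, seconds.
#' @slot target_fs amplitude sampling rate after downsampling, Hz.
#' @slot feature_fs feature sampling rate, Hz.
#' @slot bin_width response bin width, seconds (reciprocal of feature_fs).
#' @slot lags stimulus-to-response delays, seconds.
#' @slot alpha_grid candidate ridge coefficients.
#' @slot n_folds cross-validation folds.
#' @slot n_perm permutations for the temporal-shuffle null.
#' @slot rng_seed seed recorded for provenance.
#' @slot excluded_blocks block indices dropped from all analyses.
#' @slot min_contacts minimum contacts per region for a fit.
#' @slot feature_names emotion feature names.
#' @slot complex_group feature names averaged as "complex" emotions.
#' @slot basic_group feature names averaged as "basic" emotions.
#' @slot notch_q quality factor of the IIR notch.
#' @slot fold_scheme "contiguous" (default) or "random".
#' @slot contact_mode "concatenate" (default) or "average".
#' @slot perm_scheme "shuffle" (default) or "circular".
#' @seealso [pipelineConfig()]
#' @export
setClass("PipelineConfig",
    representation(line_freq = "numeric", hfb_band = "numeric",
                   filter_order = "numeric", epoch_window = "numeric",
                   baseline_window = "numeric", target_fs = "numeric",
                   feature_fs = "numeric", bin_width = "numeric",
                   lags = "numeric", alpha_grid = "numeric",
                   n_folds = "numeric", n_perm = "numeric",
                   rng_seed = "numeric", excluded_blocks = "numeric",
                   min_contacts = "numeric", feature_names = "character",
                   complex_group = "character", basic_group = "character",
                   notch_q = "numeric", fold_scheme = "character",
                   contact_mode = "character", perm_scheme = "character"))

setValidity("PipelineConfig", function(object) {
    msg <- character()
    if (object@line_freq <= 0) msg <- c(msg, "line_freq must be positive")
    if (length(object@hfb_band) != 2L || any(object@hfb_band <= 0) ||
        diff(object@hfb_band) <= 0)
        msg <- c(msg, "hfb_band must be an increasing positive pair")
    if (object@filter_order < 1) msg <- c(msg, "filter_order must be >= 1")
    if (object@target_fs <= 0 || object@feature_fs <= 0)
        msg <- c(msg, "sampling rates must be positive")
    if (object@bin_width <= 0)
        msg <- c(msg, "bin_width must be positive")
    if (abs(object@bin_width * object@feature_fs - 1) > 1e-9)
        msg <- c(msg, "bin_width must equal 1/feature_fs")
    if (any(object@lags < 0))
        msg <- c(msg, "lags must be non-negative")
    if (any(abs(object@lags * object@feature_fs -
                round(object@lags * object@feature_fs)) > 1e-9))
        msg <- c(msg, "lags must be multiples of 1/feature_fs")
    if (length(object@alpha_grid) < 1L ||
        is.unsorted(object@alpha_grid, strictly = TRUE))
        msg <- c(msg, "alpha_grid must be strictly increasing")
    if (object@n_folds < 2) msg <- c(msg, "n_folds must be >= 2")
    if (object@n_perm < 1) msg <- c(msg, "n_perm must be >= 1")
    if (anyDuplicated(object@feature_names))
        msg <- c(msg, "feature_names must be unique")
    if (!all(object@complex_group %in% object@feature_names))
        msg <- c(msg, "complex_group must be a subset of feature_names")
    if (!all(object@basic_group %in% object@feature_names))
        msg <- c(msg, "basic_group must be a subset of feature_names")
    if (!object@fold_scheme %in% c("contiguous", "random"))
        msg <- c(msg, "fold_scheme must be 'contiguous' or 'random'")
    if (!object@contact_mode %in% c("concatenate", "average"))
        msg <- c(msg, "contact_mode must be 'concatenate' or 'average'")
    if (!object@perm_scheme %in% c("shuffle", "circular"))
        msg <- c(msg, "perm_scheme must be 'shuffle' or 'circular'")
    if (length(msg)) msg else TRUE
})

#' Build a pipeline configuration
#'
#' Collects every tunable constant of the analysis. Defaults reproduce the
#' standard protocol: 50 Hz notch, 110-140 Hz fourth-order Butterworth band,
#' 0-30 s block epochs with a -0.2-0 s baseline, 400 Hz amplitude rate,
#' 2 Hz features, 500 ms bins, lags of 0/0.5/1 s, 20 ridge coefficients
#' log-spaced between 10 and 10000, fivefold cross-validation, 5000
#' permutations, the fifth music block (overall block 9 of the 13-block
#' interleaved stimulus) excluded, and at least 4 contacts per region.
#'
#' @param line_freq power-line frequency, Hz.
#' @param hfb_band two band edges, Hz.
#' @param filter_order Butterworth order of the band-pass.
#' @param epoch_window two offsets from block onset, seconds.
#' @param baseline_window two offsets from block onset, seconds (negative
#'   start; the pre-onset margin retained on epochs).
#' @param target_fs amplitude rate after downsampling, Hz.
#' @param feature_fs feature rate, Hz.
#' @param bin_width response bin width, seconds; must equal
#'   \code{1/feature_fs}.
#' @param lags delays applied to each feature, seconds.
#' @param alpha_grid strictly increasing ridge coefficients.
#' @param n_folds number of cross-validation folds.
#' @param n_perm number of temporal-shuffle permutations.
#' @param rng_seed integer seed recorded for provenance.
#' @param excluded_blocks block indices dropped everywhere.
#' @param min_contacts minimum contacts in a region for fitting.
#' @param feature_names emotion feature names (any length, unique).
#' @param complex_group,basic_group feature-name subsets averaged in the
#'   weight analysis. Set \code{complex_group} to include
#'   \code{"interest"} for the five-emotion grouping.
#' @param notch_q quality factor of the notch filter.
#' @param fold_scheme \code{"contiguous"} temporal segments (default) or
#'   \code{"random"} row folds.
#' @param contact_mode \code{"concatenate"} responses across contacts
#'   (default) or \code{"average"} them.
#' @param perm_scheme \code{"shuffle"} rows jointly (default) or
#'   \code{"circular"} shift.
#' @return a validated [PipelineConfig-class] object.
#' @examples
#' cfg <- pipelineConfig()
#' cfg@alpha_grid[c(1, 20)]   # 10 and 10000
#' @export
pipelineConfig <- function(line_freq = 50, hfb_band = c(110, 140),
                           filter_order = 4, epoch_window = c(0, 30),
                           baseline_window = c(-0.2, 0), target_fs = 400,
                           feature_fs = 2, bin_width = 1 / feature_fs,
                           lags = c(0, 0.5, 1),
                           alpha_grid = alphaGrid(),
                           n_folds = 5, n_perm = 5000, rng_seed = 1,
                           excluded_blocks = 9, min_contacts = 4,
                           feature_names = emotionVocabulary(),
                           complex_group = c("guilt", "embarrassment",
                                             "pride", "envy"),
                           basic_group = c("joy", "sadness", "fear",
                                           "anger", "disgust", "surprise"),
                           notch_q = 30, fold_scheme = "contiguous",
                           contact_mode = "concatenate",
                           perm_scheme = "shuffle") {
    new("PipelineConfig", line_freq = line_freq, hfb_band = hfb_band,
        filter_order = filter_order, epoch_window = epoch_window,
        baseline_window = baseline_window, target_fs = target_fs,
        feature_fs = feature_fs, bin_width = bin_width, lags = lags,
        alpha_grid = alpha_grid, n_folds = n_folds, n_perm = n_perm,
        rng_seed = rng_seed, excluded_blocks = excluded_blocks,
        min_contacts = min_contacts, feature_names = feature_names,
        complex_group = complex_group, basic_group = basic_group,
        notch_q = notch_q, fold_scheme = fold_scheme,
        contact_mode = contact_mode, perm_scheme = perm_scheme)
}

#' Candidate ridge coefficients
#'
#' Log-spaced grid of regularization coefficients searched when selecting
#' the single shared ridge penalty.
#'
#' @param n number of grid points.
#' @param range lower and upper endpoints (inclusive).
#' @return strictly increasing numeric vector with exact endpoints.
#' @examples
#' alphaGrid()[c(1, 20)]
#' @export
alphaGrid <- function(n = 20, range = c(10, 10000)) {
    stopifnot(n >= 2, length(range) == 2L, all(range > 0),
              range[2L] > range[1L])
    g <- exp(seq(log(range[1L]), log(range[2L]), length.out = n))
    g[1L] <- range[1L]
    g[n] <- range[2L]
    g
}
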