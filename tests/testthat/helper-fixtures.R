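# Shared fixtures: tiny deterministic objects used across test files.

# A small feature vocabulary that still contains the emotion groups used by
# the weight analysis.
tinyVocab <- function() {
    c("guilt", "embarrassment", "pride", "envy", "interest",
      "joy", "sadness", "fear", "anger", "disgust", "surprise", "calmness")
}

tinyConfig <- function(...) {
    args <- utils::modifyList(list(feature_names = tinyVocab(),
                                   min_contacts = 1), list(...))
    do.call(pipelineConfig, args)
}

# Deterministic FeatureTimecourse: n_blocks x n_bins x features, values
# filled from a fixed sequence, conditions alternating music/speech.
gridFeatures <- function(n_blocks = 2, n_bins = 10, fs = 2,
                         names = tinyVocab(), block_index = NULL) {
    nf <- length(names)
    vals <- array(rep(seq(0, 1, length.out = n_bins), n_blocks * nf),
                  dim = c(n_bins, n_blocks, nf))
    vals <- aperm(vals, c(2L, 1L, 3L))
    dimnames(vals) <- list(NULL, NULL, names)
    if (is.null(block_index)) block_index <- seq_len(n_blocks)
    new("FeatureTimecourse", values = vals, fs = fs,
        blockMeta = data.frame(
            block_index = block_index,
            condition = ifelse(block_index %% 2L == 1L, "music", "speech"),
            stringsAsFactors = FALSE))
}

# Direct normal-equation ridge oracle with an unpenalized intercept:
# solve the (p+1) x (p+1) augmented system with the penalty on the
# non-intercept block only.
ridgeOracle <- function(X, y, alpha) {
    Xa <- cbind(1, X)
    p <- ncol(X)
    pen <- diag(c(0, rep(alpha, p)))
    beta <- solve(crossprod(Xa) + pen, crossprod(Xa, y))
    list(weights = as.numeric(beta[-1L]), intercept = beta[1L])
}

# A small raw recording: per-channel tones/noise at a given rate.
toneRecording <- function(freqs, fs = 2048, dur = 5, amp = 1,
                          regions = NULL) {
    t <- seq(0, dur - 1 / fs, by = 1 / fs)
    data <- vapply(freqs, function(f) amp * cos(2 * pi * f * t),
                   numeric(length(t)))
    colnames(data) <- paste0("ch", seq_along(freqs))
    ch <- data.frame(name = colnames(data),
                     region = regions %||% rep("other", length(freqs)),
                     hemisphere = "L", status = "good",
                     stringsAsFactors = FALSE)
    new("IeegRecording", data = data, fs = fs, channels = ch)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
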