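# Synthetic-data generator: stimulus features, ground-truth-coupled
# responses, raw band-modulated signals, and whole cohorts. Everything is
# deterministic under a seed, and every object passes the package's own
# validators, so each pipeline stage and statistical claim is testable
# without any recorded data.

#' Standard 13-block interleaved stimulus events
#'
#' Blocks of \code{duration} seconds, music on odd positions and speech on
#' even ones (7 music + 6 speech for the default 13), with \code{start}
#' seconds of lead-in before the first onset. Consecutive blocks are
#' separated by \code{gap} seconds of stimulus-free signal so that the
#' pre-onset baseline window samples ongoing activity rather than the
#' preceding block's content.
#'
#' @param n_blocks number of blocks.
#' @param duration block duration, seconds.
#' @param start onset of the first block, seconds.
#' @param gap stimulus-free interval between blocks, seconds.
#' @return validated events data.frame.
#' @export
standardEvents <- function(n_blocks = 13, duration = 30, start = 2,
                           gap = 1) {
    ev <- data.frame(
        onset = start + (seq_len(n_blocks) - 1) * (duration + gap),
        duration = duration,
        condition = ifelse(seq_len(n_blocks) %% 2L == 1L,
                           "music", "speech"),
        block_index = seq_len(n_blocks),
        stringsAsFactors = FALSE)
    validateEvents(ev)
}

# AR(1) series of length n with (asymptotically) unit marginal variance.
ar1Unit <- function(n, phi) {
    as.numeric(stats::filter(stats::rnorm(n, sd = sqrt(1 - phi^2)), phi,
                             method = "recursive"))
}

#' Simulate emotion feature time courses
#'
#' Per block and feature: smoothed Gaussian noise (AR(1) with a ~2 s
#' correlation time) plus sparse positive burst events mimicking expression
#' episodes, pushed through a logistic squashing into \eqn{[0, 1]}. The
#' face-free block (the fifth music block, overall index 9, by default)
#' is emitted as all zeros.
#'
#' @param n_blocks number of blocks (conditions follow the interleaved
#'   music/speech convention of [standardEvents()]).
#' @param seed RNG seed.
#' @param feature_names feature names (third dimension).
#' @param fs feature rate, Hz.
#' @param duration block duration, seconds.
#' @param face_free_blocks block indices emitted with no facial activity.
#' @param ar_time correlation time of the smooth component, seconds.
#' @param burst_rate expected bursts per second per feature.
#' @return a [FeatureTimecourse-class] covering all \code{n_blocks} blocks.
#' @examples
#' ft <- simulateFeatures(seed = 7)
#' range(ft@values)
#' @export
simulateFeatures <- function(n_blocks = 13, seed = 1,
                             feature_names = emotionVocabulary(), fs = 2,
                             duration = 30,
                             face_free_blocks =
                                 if (n_blocks >= 9) 9 else integer(),
                             ar_time = 2, burst_rate = 0.1) {
    set.seed(seed)
    n <- round(duration * fs)
    nf <- length(feature_names)
    phi <- exp(-1 / (ar_time * fs))
    arr <- array(0, dim = c(n_blocks, n, nf),
                 dimnames = list(NULL, NULL, feature_names))
    tker <- exp(-(0:round(2 * fs)) / fs)     # 1 s decay burst kernel
    for (b in seq_len(n_blocks)) {
        for (f in seq_len(nf)) {
            z <- ar1Unit(n, phi)
            nb <- stats::rpois(1L, burst_rate * duration)
            if (nb > 0) {
                for (k in seq_len(nb)) {
                    at <- sample.int(n, 1L)
                    amp <- stats::runif(1L, 1.5, 3)
                    idx <- at:min(n, at + length(tker) - 1L)
                    z[idx] <- z[idx] + amp * tker[seq_along(idx)]
                }
            }
            arr[b, , f] <- stats::plogis(1.2 * z - 1.5)
        }
    }
    if (length(face_free_blocks))
        arr[intersect(face_free_blocks, seq_len(n_blocks)), , ] <- 0
    new("FeatureTimecourse", values = arr, fs = fs,
        blockMeta = data.frame(
            block_index = seq_len(n_blocks),
            condition = ifelse(seq_len(n_blocks) %% 2L == 1L,
                               "music", "speech"),
            stringsAsFactors = FALSE))
}

#' Expand features to per-face frame scores
#'
#' Turns a 2 Hz feature time course into a long per-frame, per-face score
#' table at video rate, for testing [aggregateFaces()] and
#' [resampleFeatures()]: one face carries the block's feature value, the
#' others lower random fractions of it, so the across-face maximum
#' recovers the original course. Face-free (all-zero) blocks emit no rows.
#'
#' @param features a [FeatureTimecourse-class] object.
#' @param events matching events data.frame (for absolute frame times).
#' @param fps frame rate.
#' @param n_faces faces per frame.
#' @param seed RNG seed.
#' @return data.frame with columns time, face_id and one per feature.
#' @export
expandFaces <- function(features, events, fps = 25, n_faces = 2,
                        seed = 1) {
    set.seed(seed)
    d <- dim(features@values)
    fnames <- dimnames(features@values)[[3L]]
    out <- list()
    for (b in seq_len(d[1L])) {
        if (all(features@values[b, , ] == 0)) next
        bi <- features@blockMeta$block_index[b]
        onset <- events$onset[events$block_index == bi]
        dur <- events$duration[events$block_index == bi]
        ft <- seq(0, dur - 1 / fps, by = 1 / fps)
        bin <- pmin(floor(ft * features@fs) + 1L, d[2L])
        vals <- features@values[b, bin, , drop = TRUE]
        for (face in seq_len(n_faces)) {
            frac <- if (face == 1L) 1 else
                stats::runif(length(ft), 0, 0.8)
            df <- data.frame(time = onset + ft, face_id = face)
            df[fnames] <- vals * frac
            out[[length(out) + 1L]] <- df
        }
    }
    res <- do.call(rbind, out)
    res[order(res$time, res$face_id), , drop = FALSE]
}

#' Ground truth for a synthetic encoding dataset
#'
#' @param feature_names feature names.
#' @param lags delays, seconds.
#' @param seed RNG seed for the weight draw (ignored when \code{weights}
#'   given).
#' @param weights optional features x lags matrix. When NULL, a sparse
#'   realistic set is drawn: about half the features couple at all, and a
#'   coupled feature carries a signed Gaussian amplitude spread over the
#'   lags by a smooth positive profile (temporal response functions are
#'   sign-consistent and smooth across neighbouring delays).
#' @param snr ratio of feature-driven to noise variance in the response.
#' @param ar AR(1) coefficient of the response noise (in \eqn{[0, 1)}).
#' @param weight_sd scale of the drawn weights.
#' @return list of class \code{GroundTruth}: \code{weights} (features x
#'   lags), \code{snr}, \code{ar}, \code{lags}.
#' @export
groundTruth <- function(feature_names = emotionVocabulary(),
                        lags = c(0, 0.5, 1), seed = 1, weights = NULL,
                        snr = 1, ar = 0.3, weight_sd = 1) {
    stopifnot(snr >= 0, ar >= 0, ar < 1)
    if (is.null(weights)) {
        set.seed(seed)
        nf <- length(feature_names)
        nl <- length(lags)
        amp <- stats::rnorm(nf, sd = weight_sd) *
            stats::rbinom(nf, 1L, 0.5)
        prof <- matrix(stats::runif(nf * nl, 0.3, 1), nf)
        prof <- prof / sqrt(rowSums(prof^2))
        weights <- matrix(amp * prof, nf,
                          dimnames = list(feature_names,
                                          paste0("lag", lags)))
    }
    structure(list(weights = weights, snr = snr, ar = ar, lags = lags),
              class = "GroundTruth")
}

# Vectorize a features x lags weight matrix in the design's feature-major
# column order.
vecWeights <- function(weights) as.numeric(t(weights))

# Feature-driven signal for the blocks of a FeatureTimecourse, block-major,
# optionally scaled per block by a condition multiplier.
truthSignal <- function(features, truth, cond_mult = c(speech = 1,
                                                       music = 1)) {
    shifts <- as.integer(round(truth$lags * features@fs))
    X <- lagExpand(features@values, shifts)
    s <- as.numeric(X %*% vecWeights(truth$weights))
    n_bins <- dim(features@values)[2L]
    mult <- cond_mult[features@blockMeta$condition]
    s * rep(unname(mult), each = n_bins)
}

#' Simulate binned responses with known linear coupling
#'
#' Generates \eqn{y(t) = \sum_f \sum_\tau w_{f\tau} x_f(t-\tau) +
#' \varepsilon(t)} per contact, with independent AR(1) noise per contact
#' scaled so that var(signal)/var(noise) equals the ground truth's
#' \code{snr} (noise SD 1 when the weights are all zero).
#'
#' @param features a [FeatureTimecourse-class] (already reduced to the
#'   retained blocks).
#' @param truth a [groundTruth()] object with matching dimensions.
#' @param seed RNG seed.
#' @param n_contacts number of contacts (response columns).
#' @param cond_mult named multipliers applied to the signal per condition.
#' @param contact_names optional column names.
#' @param noise_sd optional fixed noise SD, overriding the snr-derived
#'   scaling; [simulateCohort()] uses this so that every subject shares one
#'   noise level (per-subject snr-scaling would tie the noise floor of the
#'   weight estimates to each subject's coupling strength).
#' @return a [BinnedResponse-class] at the feature rate.
#' @export
simulateResponse <- function(features, truth, seed = 1, n_contacts = 1,
                             cond_mult = c(speech = 1, music = 1),
                             contact_names = NULL, noise_sd = NULL) {
    d <- dim(features@values)
    if (nrow(truth$weights) != d[3L] ||
        ncol(truth$weights) != length(truth$lags))
        stop("ground-truth weight dimensions do not match features x lags")
    s <- truthSignal(features, truth, cond_mult)
    set.seed(seed)
    sd_s <- stats::sd(s)
    if (is.null(noise_sd))
        noise_sd <- if (sd_s > 0 && truth$snr > 0)
            sd_s / sqrt(truth$snr) else 1
    n <- length(s)
    y <- matrix(0, n, n_contacts)
    for (j in seq_len(n_contacts))
        y[, j] <- s + noise_sd * ar1Unit(n, truth$ar)
    colnames(y) <- contact_names %||%
        paste0("c", seq_len(n_contacts))
    n_bins <- d[2L]
    new("BinnedResponse", y = y, rowMeta = data.frame(
        block_index = rep(features@blockMeta$block_index, each = n_bins),
        bin = rep(seq_len(n_bins), d[1L]),
        condition = rep(features@blockMeta$condition, each = n_bins),
        stringsAsFactors = FALSE))
}

#' Simulate a raw recording with a known HFB envelope
#'
#' Builds, per channel, band-limited 110-140 Hz carrier noise
#' amplitude-modulated by the target envelope, on top of pink background
#' noise and a 50 Hz line component. Running the result through
#' [preprocessRecording()] recovers an HFB trace that follows the target
#' envelope.
#'
#' @param envelope non-negative matrix, envelope samples x channels, at
#'   \code{env_fs}.
#' @param env_fs envelope sampling rate, Hz (>= 2).
#' @param fs output sampling rate, Hz; must exceed twice the carrier band.
#' @param seed RNG seed.
#' @param band carrier band, Hz.
#' @param background_sd SD of the pink background.
#' @param line_amp amplitude of the 50 Hz line component.
#' @param channel_names optional channel names.
#' @return an [IeegRecording-class] object.
#' @export
simulateRaw <- function(envelope, env_fs, fs = 2048, seed = 1,
                        band = c(110, 140), background_sd = 0.3,
                        line_amp = 0.5, channel_names = NULL) {
    envelope <- as.matrix(envelope)
    if (min(envelope) < 0) stop("envelope must be non-negative")
    if (fs <= 2 * band[2L])
        stop("fs too low for the carrier band")
    set.seed(seed)
    n <- round(nrow(envelope) / env_fs * fs)
    t <- (seq_len(n) - 1L) / fs
    nch <- ncol(envelope)
    data <- matrix(0, n, nch)
    fc <- mean(band)
    hw <- diff(band) / 2
    lp <- signal::butter(2, 5 / (fs / 2), type = "low")
    for (j in seq_len(nch)) {
        # constant-amplitude carrier: a unit cosine whose instantaneous
        # frequency wanders slowly inside the band, so the target envelope
        # is exactly the carrier's envelope and survives re-filtering
        df <- signal::filtfilt(lp, stats::rnorm(n))
        df <- df / stats::sd(df) * hw / 3
        df <- pmin(pmax(df, -0.9 * hw), 0.9 * hw)
        carrier <- cos(cumsum(2 * pi * (fc + df) / fs) +
                       stats::runif(1L, 0, 2 * pi))
        # zero-order hold: each envelope sample governs its whole
        # [k/env_fs, (k+1)/env_fs) interval, matching the half-open bin
        # convention of the analysis
        env_up <- stats::approx((seq_len(nrow(envelope)) - 1L) / env_fs,
                                envelope[, j], xout = t,
                                method = "constant", f = 0, rule = 2)$y
        env_up[env_up < 0] <- 0
        data[, j] <- env_up * carrier +
            background_sd * pinkNoise(n) +
            line_amp * sin(2 * pi * 50 * t + stats::runif(1L, 0, 2 * pi))
    }
    nm <- channel_names %||% paste0("ch", seq_len(nch))
    colnames(data) <- nm
    new("IeegRecording", data = data, fs = fs,
        channels = defaultChannelTable(nm), unit = "signal")
}

retainBlocks <- function(features, excluded) {
    keep <- !(features@blockMeta$block_index %in% excluded)
    new("FeatureTimecourse",
        values = features@values[keep, , , drop = FALSE],
        fs = features@fs,
        blockMeta = features@blockMeta[keep, , drop = FALSE])
}

#' Simulate one subject
#'
#' Generates the full data for a single synthetic subject: stimulus events,
#' feature time courses, ground-truth weights, and either binned responses
#' (\code{level = "binned"}, the default) or a raw multichannel recording
#' whose 110-140 Hz envelope carries the coupling
#' (\code{level = "raw"}). At raw level the per-contact envelope is
#' \eqn{e(t) = \max(1 + \kappa(z(t) + \eta(t)), 0.05)} with \eqn{z} the
#' standardized feature-driven signal and \eqn{\eta} AR(1) noise of
#' variance \eqn{1/\mathrm{snr}}.
#'
#' @param seed RNG seed.
#' @param n_blocks stimulus blocks.
#' @param n_contacts contacts in \code{region}.
#' @param region region label for the contacts.
#' @param snr feature-driven to noise variance ratio.
#' @param level \code{"binned"} or \code{"raw"}.
#' @param truth optional [groundTruth()] (drawn from \code{seed} if NULL).
#' @param config a [PipelineConfig-class] object.
#' @param id,age,group subject metadata.
#' @param mod_depth envelope modulation depth \eqn{\kappa} (raw level).
#' @return list with \code{events}, \code{features} (all blocks),
#'   \code{truth}, \code{subject}, and \code{response} (binned level) or
#'   \code{recording} (raw level).
#' @export
simulateSubject <- function(seed = 1, n_blocks = 13, n_contacts = 6,
                            region = "pSTC", snr = 2,
                            level = c("binned", "raw"), truth = NULL,
                            config = pipelineConfig(), id = "s01",
                            age = 25,
                            group = if (age <= 10) "childhood"
                                    else "post_childhood",
                            mod_depth = 0.5) {
    level <- match.arg(level)
    events <- standardEvents(n_blocks, diff(config@epoch_window),
                             start = 2)
    features <- simulateFeatures(n_blocks, seed = seed,
                                 feature_names = config@feature_names,
                                 fs = config@feature_fs,
                                 duration = diff(config@epoch_window))
    if (is.null(truth))
        truth <- groundTruth(config@feature_names, config@lags,
                             seed = seed + 1L, snr = snr)
    retained <- retainBlocks(features, config@excluded_blocks)
    subject <- list(id = id, age = age, group = group)
    if (level == "binned") {
        resp <- simulateResponse(retained, truth, seed = seed + 2L,
                                 n_contacts = n_contacts,
                                 contact_names = paste0(region,
                                                        seq_len(n_contacts)))
        return(list(events = events, features = features, truth = truth,
                    subject = subject, response = resp))
    }
    # raw level: envelope over the full recording timeline at feature rate
    set.seed(seed + 2L)
    fs_env <- config@feature_fs
    total <- max(events$onset + events$duration) + 2
    n_env <- round(total * fs_env)
    s <- truthSignal(retained, truth)
    z <- (s - mean(s)) / stats::sd(s)
    n_bins <- dim(retained@values)[2L]
    env <- matrix(1, n_env, n_contacts)
    for (j in seq_len(n_contacts)) {
        eta <- ar1Unit(n_env, truth$ar) *
            (if (snr > 0) 1 / sqrt(snr) else 1)
        e <- 1 + mod_depth * eta
        for (b in seq_len(nrow(retained@blockMeta))) {
            bi <- retained@blockMeta$block_index[b]
            onset <- events$onset[events$block_index == bi]
            bins <- round(onset * fs_env) + seq_len(n_bins)
            e[bins] <- e[bins] + mod_depth *
                z[(b - 1L) * n_bins + seq_len(n_bins)]
        }
        env[, j] <- pmax(e, 0.05)
    }
    rec <- simulateRaw(env, fs_env, fs = 2048, seed = seed + 3L,
                       band = config@hfb_band,
                       channel_names = paste0(region,
                                              seq_len(n_contacts)))
    rec@channels$region <- region
    rec@subject <- subject
    list(events = events, features = features, truth = truth,
         subject = subject, recording = rec)
}

#' Simulate a multi-subject study
#'
#' All subjects watch the same synthetic stimulus (one shared feature time
#' course). Each subject's true weights are drawn from a common template;
#' on the designated \code{slope_features} the per-entry coupling is
#' \code{base_coupling + age_slope * age + jitter}, so the cohort carries a
#' known weight-age dependence. Region-, group- and condition-specific
#' coupling multipliers allow contrasts such as coupling present in one
#' group's DLPFC only, or under speech only.
#'
#' @param n_subjects number of subjects (>= 3) when \code{ages} is NULL.
#' @param age_range ages drawn uniformly in this range.
#' @param ages optional explicit ages (overrides \code{n_subjects}).
#' @param seed RNG seed (the whole study is reproducible from it).
#' @param regions regions simulated per subject.
#' @param n_contacts contacts per region (single number or named vector).
#' @param snr feature-driven to noise variance ratio.
#' @param age_slope per-year increase of the designated features' coupling.
#' @param slope_features features whose coupling depends on age.
#' @param base_coupling age-independent part of the designated coupling.
#' @param jitter_sd SD of the per-subject jitter on designated entries.
#' @param template_sd SD of the shared sparse template weights.
#' @param group_coupling optional list \code{region -> c(childhood =,
#'   post_childhood =)} multipliers.
#' @param cond_coupling optional list \code{group -> c(speech =, music =)}
#'   multipliers.
#' @param config a [PipelineConfig-class] object.
#' @return list of class \code{SyntheticStudy}: \code{subjects}
#'   (data.frame), \code{events}, \code{features} (retained blocks),
#'   \code{responses[[id]][[region]]} ([BinnedResponse-class]) and
#'   \code{truth[[id]][[region]]} ([groundTruth()] objects).
#' @export
simulateCohort <- function(n_subjects = 12, age_range = c(5, 55),
                           ages = NULL, seed = 1, regions = "pSTC",
                           n_contacts = 6, snr = 2, age_slope = 0,
                           slope_features = c("guilt", "embarrassment",
                                              "pride", "envy"),
                           base_coupling = 0.1, jitter_sd = 0.1,
                           template_sd = 0.5, group_coupling = NULL,
                           cond_coupling = NULL,
                           config = pipelineConfig()) {
    set.seed(seed)
    if (is.null(ages)) {
        if (n_subjects < 3L) stop("need at least 3 subjects")
        if (diff(range(age_range)) <= 0) stop("degenerate age range")
        ages <- stats::runif(n_subjects, age_range[1L], age_range[2L])
    }
    n_subjects <- length(ages)
    ids <- sprintf("s%02d", seq_len(n_subjects))
    groups <- ifelse(ages <= 10, "childhood", "post_childhood")
    subjects <- data.frame(id = ids, age = ages, group = groups,
                           stringsAsFactors = FALSE)
    events <- standardEvents(13, diff(config@epoch_window), start = 2)
    features <- simulateFeatures(13, seed = seed,
                                 feature_names = config@feature_names,
                                 fs = config@feature_fs,
                                 duration = diff(config@epoch_window))
    retained <- retainBlocks(features, config@excluded_blocks)
    if (length(n_contacts) == 1L)
        n_contacts <- stats::setNames(rep(n_contacts, length(regions)),
                                      regions)
    fn <- config@feature_names
    nl <- length(config@lags)
    tamp <- stats::rnorm(length(fn), sd = template_sd) *
        stats::rbinom(length(fn), 1L, 0.5)
    tprof <- matrix(stats::runif(length(fn) * nl, 0.3, 1), length(fn))
    tprof <- tprof / sqrt(rowSums(tprof^2))
    template <- matrix(tamp * tprof, length(fn),
                       dimnames = list(fn, paste0("lag", config@lags)))
    sub_seeds <- sample.int(1e8L, n_subjects * length(regions))
    # one noise level for the whole cohort, anchored at the mean-age
    # subject's signal: per-subject snr scaling would make the noise floor
    # of every |weight| estimate grow with coupling strength (and hence
    # with age), confounding the weight-age analysis
    Wref <- template
    if (length(slope_features))
        Wref[slope_features, ] <- base_coupling +
            age_slope * mean(ages)
    s_ref <- truthSignal(retained, groundTruth(fn, config@lags,
                                               weights = Wref, snr = snr))
    noise_sd <- if (stats::sd(s_ref) > 0 && snr > 0)
        stats::sd(s_ref) / sqrt(snr) else 1
    responses <- list()
    truths <- list()
    k <- 0L
    for (i in seq_len(n_subjects)) {
        responses[[ids[i]]] <- list()
        truths[[ids[i]]] <- list()
        for (reg in regions) {
            k <- k + 1L
            W <- template
            if (length(slope_features)) {
                val <- base_coupling + age_slope * ages[i]
                W[slope_features, ] <- val +
                    stats::rnorm(length(slope_features) * nl,
                                 sd = jitter_sd)
            }
            gmult <- 1
            if (!is.null(group_coupling) && reg %in% names(group_coupling))
                gmult <- group_coupling[[reg]][[groups[i]]]
            W <- W * gmult
            cm <- c(speech = 1, music = 1)
            if (!is.null(cond_coupling) &&
                groups[i] %in% names(cond_coupling))
                cm <- cond_coupling[[groups[i]]]
            truth <- groundTruth(fn, config@lags, weights = W, snr = snr)
            resp <- simulateResponse(
                retained, truth, seed = sub_seeds[k],
                n_contacts = n_contacts[[reg]], cond_mult = cm,
                contact_names = paste0(reg, seq_len(n_contacts[[reg]])),
                noise_sd = noise_sd)
            responses[[ids[i]]][[reg]] <- resp
            truths[[ids[i]]][[reg]] <- truth
        }
    }
    structure(list(subjects = subjects, events = events,
                   features = retained, responses = responses,
                   truth = truths, seed = seed),
              class = "SyntheticStudy")
}

#' Write a synthetic study to disk
#'
#' Materializes a [simulateCohort()] study as plain files: events.tsv,
#' subjects.tsv, features.tsv (2 Hz, absolute times), one response binary +
#' sidecar per subject/region, and ground_truth.json.
#'
#' @param study a \code{SyntheticStudy}.
#' @param dir output directory.
#' @return invisibly, \code{dir}.
#' @export
writeStudy <- function(study, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ev <- study$events
    names(ev)[names(ev) == "condition"] <- "trial_type"
    utils::write.table(ev, file.path(dir, "events.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(study$subjects, file.path(dir, "subjects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ft <- study$features
    d <- dim(ft@values)
    rows <- list()
    for (b in seq_len(d[1L])) {
        bi <- ft@blockMeta$block_index[b]
        onset <- study$events$onset[study$events$block_index == bi]
        df <- data.frame(time = onset + (seq_len(d[2L]) - 1L) / ft@fs)
        df[dimnames(ft@values)[[3L]]] <- ft@values[b, , ]
        rows[[b]] <- df
    }
    utils::write.table(do.call(rbind, rows),
                       file.path(dir, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    truth_out <- lapply(study$truth, function(regs)
        lapply(regs, function(tr)
            list(weights = tr$weights, snr = tr$snr, ar = tr$ar,
                 lags = tr$lags)))
    jsonlite::write_json(truth_out, file.path(dir, "ground_truth.json"),
                         digits = NA, auto_unbox = TRUE)
    for (sid in names(study$responses)) {
        for (reg in names(study$responses[[sid]])) {
            resp <- study$responses[[sid]][[reg]]
            base <- file.path(dir, sprintf("response_%s_%s", sid, reg))
            writeBin(as.numeric(resp@y), paste0(base, ".bin"), size = 8L,
                     endian = "little")
            jsonlite::write_json(
                list(contacts = colnames(resp@y),
                     row_meta = resp@rowMeta),
                paste0(base, ".json"), digits = NA, auto_unbox = TRUE)
        }
    }
    invisible(dir)
}

#' Read a study directory written by [writeStudy()]
#'
#' @param dir directory holding events.tsv, subjects.tsv, features.tsv and
#'   per-subject response binaries.
#' @param config a [PipelineConfig-class] (for feature names and rates).
#' @return list with \code{subjects}, \code{events}, \code{features} and
#'   \code{responses}, the shape consumed by [fitAll()].
#' @export
readStudy <- function(dir, config = pipelineConfig()) {
    events <- readEvents(file.path(dir, "events.tsv"))
    subjects <- readSubjects(file.path(dir, "subjects.tsv"))
    raw <- readFeatureTable(file.path(dir, "features.tsv"),
                            config@feature_names)
    features <- resampleFeatures(raw, events,
                                 target_fs = config@feature_fs,
                                 feature_names = config@feature_names,
                                 excluded_blocks = config@excluded_blocks)
    responses <- list()
    for (f in list.files(dir, "^response_.*\\.json$")) {
        meta <- jsonlite::read_json(file.path(dir, f),
                                    simplifyVector = TRUE)
        binf <- file.path(dir, sub("\\.json$", ".bin", f))
        y <- matrix(readBin(binf, "double", file.size(binf) / 8L,
                            size = 8L, endian = "little"),
                    ncol = length(meta$contacts))
        colnames(y) <- meta$contacts
        parts <- strsplit(sub("^response_(.*)\\.json$", "\\1", f),
                          "_")[[1L]]
        sid <- parts[1L]
        reg <- parts[2L]
        responses[[sid]][[reg]] <- new("BinnedResponse", y = y,
                                       rowMeta = as.data.frame(
                                           meta$row_meta))
    }
    list(subjects = subjects, events = events, features = features,
         responses = responses)
}
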