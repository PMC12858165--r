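# The synthetic-data generator: determinism, stimulus structure, coupling
# bookkeeping and consistency with the analysis pipeline.

test_that("feature simulation is bounded, smooth and seed-deterministic", {
    ft <- simulateFeatures(seed = 7)
    expect_s4_class(ft, "FeatureTimecourse")
    expect_true(validObject(ft))
    expect_gte(min(ft@values), 0)
    expect_lte(max(ft@values), 1)
    expect_equal(dim(ft@values), c(13L, 60L, 48L))
    expect_true(all(ft@values[9, , ] == 0))   # face-free fifth music block
    expect_equal(ft@blockMeta$condition[c(1, 2, 9)],
                 c("music", "speech", "music"))

    ft2 <- simulateFeatures(seed = 7)
    expect_identical(ft@values, ft2@values)

    # lag-1 autocorrelation above 0.5 at 2 Hz under default smoothing
    ac <- mean(vapply(1:48, function(f) {
        v <- as.numeric(t(ft@values[-9, , f]))
        cor(v[-1], v[-length(v)])
    }, 0))
    expect_gt(ac, 0.5)
})

test_that("per-face expansion is recovered by aggregation + resampling", {
    cfg <- tinyConfig()
    ev <- standardEvents(3)
    ft <- simulateFeatures(3, seed = 8, feature_names = tinyVocab(),
                           face_free_blocks = integer())
    frames <- expandFaces(ft, ev, fps = 25, n_faces = 3, seed = 9)
    expect_true(all(c("time", "face_id", tinyVocab()) %in% names(frames)))
    agg <- aggregateFaces(frames, feature_names = tinyVocab())
    raw <- data.frame(time = attr(agg, "time"))
    raw[tinyVocab()] <- agg
    back <- resampleFeatures(raw, ev, feature_names = tinyVocab())
    expect_equal(back@values, ft@values, tolerance = 1e-9)
})

test_that("response simulation respects the coupling bookkeeping", {
    cfg <- tinyConfig()
    ft <- simulateFeatures(30, seed = 10, feature_names = tinyVocab(),
                           face_free_blocks = integer())
    tr0 <- groundTruth(tinyVocab(), cfg@lags,
                       weights = matrix(0, 12, 3), snr = 0)
    r0 <- simulateResponse(ft, tr0, seed = 11)
    expect_equal(sd(r0@y), 1, tolerance = 0.1)   # pure unit AR(1) noise

    tr <- groundTruth(tinyVocab(), cfg@lags, seed = 12, snr = 1)
    r1 <- simulateResponse(ft, tr, seed = 13)
    s <- hfbEncode:::truthSignal(ft, tr)
    noise <- r1@y[, 1] - s
    expect_equal(var(s) / var(noise), 1, tolerance = 0.1)

    # noiseless limit: the fit is essentially perfect
    trh <- groundTruth(tinyVocab(), cfg@lags, seed = 12, snr = 1e8)
    rh <- simulateResponse(ft, trh, seed = 14)
    des <- buildDesignMatrix(ft, cfg@lags)
    ds <- concatenateContacts(des, rh)
    fit <- crossvalFit(ds$X, ds$y, 1e-4, base = ds$base)
    expect_gt(meanR(fit), 0.99)
    rec <- cor(colMeans(abs(fit@weights)),
               abs(hfbEncode:::vecWeights(trh$weights)))
    expect_gt(rec, 0.95)

    expect_error(simulateResponse(ft, groundTruth("joy", 0, seed = 1)),
                 "dimensions")
})

test_that("raw synthesis carries the target envelope into the HFB band", {
    # constant envelope: extracted amplitude nearly constant
    const <- simulateRaw(matrix(1, 40, 1), env_fs = 2, seed = 15)
    amp <- extractHFB(const)@data[, 1]
    i <- (0.2 * 2048):(19.8 * 2048)
    expect_lt(sd(amp[i]) / mean(amp[i]), 0.2)

    # zero envelope: only the weak background remains
    none <- simulateRaw(matrix(0, 40, 1), env_fs = 2, seed = 15)
    amp0 <- extractHFB(none)@data[, 1]
    expect_lt(mean(amp0[i]), 0.2 * mean(amp[i]))

    # slow sinusoidal envelope: normalized HFB follows its z-score
    # (six channels: the common-average reference mixes carriers across
    # channels, and its envelope distortion shrinks with channel count)
    tt <- seq(0, 39.5, by = 0.5)
    g <- 1 + 0.8 * sin(2 * pi * tt / 20)
    rec <- simulateRaw(matrix(g, length(g), 6), env_fs = 2, seed = 16,
                       background_sd = 0.1)
    ev <- data.frame(onset = 2, duration = 30, condition = "speech",
                     block_index = 1)
    ep <- preprocessRecording(rec, ev, tinyConfig(
        excluded_blocks = numeric()))
    hfb <- ep@data[1, 1, -seq_len(80)]
    gt <- g[findInterval(2 + (seq_along(hfb) - 1) / 400, tt)]
    expect_gt(cor(hfb, gt), 0.8)

    expect_error(simulateRaw(matrix(-1, 10, 1), 2), "non-negative")
    expect_error(simulateRaw(matrix(1, 10, 1), 2, fs = 200), "too low")
})

test_that("cohorts are reproducible and pass the package validators", {
    cfg <- tinyConfig()
    st <- simulateCohort(ages = c(7, 20, 33), seed = 17,
                         regions = "pSTC", n_contacts = 2, snr = 2,
                         config = cfg)
    st2 <- simulateCohort(ages = c(7, 20, 33), seed = 17,
                          regions = "pSTC", n_contacts = 2, snr = 2,
                          config = cfg)
    expect_identical(st$responses, st2$responses)
    expect_identical(st$features@values, st2$features@values)

    expect_true(validObject(st$features))
    for (sid in names(st$responses))
        expect_true(validObject(st$responses[[sid]][["pSTC"]]))
    expect_equal(hfbEncode:::validateEvents(st$events), st$events)
    expect_equal(st$subjects$group, c("childhood", "post_childhood",
                                      "post_childhood"))
    expect_false(9 %in% st$features@blockMeta$block_index)

    expect_error(simulateCohort(n_subjects = 2, config = cfg),
                 "at least 3")
    expect_error(simulateCohort(age_range = c(10, 10), config = cfg),
                 "degenerate")
})

test_that("a written study is readable with the package's own readers", {
    cfg <- tinyConfig()
    st <- simulateCohort(ages = c(7, 20, 33), seed = 18,
                         regions = "pSTC", n_contacts = 2, snr = 2,
                         config = cfg)
    dir <- withr::local_tempdir()
    writeStudy(st, dir)
    ev <- readEvents(file.path(dir, "events.tsv"))
    expect_equal(ev$condition, st$events$condition)
    subj <- readSubjects(file.path(dir, "subjects.tsv"))
    expect_equal(subj$id, st$subjects$id)
    feats <- readFeatureTable(file.path(dir, "features.tsv"),
                              tinyVocab())
    expect_equal(nrow(feats), 12 * 60)
    truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                 simplifyVector = TRUE)
    expect_equal(names(truth), st$subjects$id)
})
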