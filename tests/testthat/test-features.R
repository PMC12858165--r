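# Feature aggregation, resampling, lagged design construction, response
# binning and per-condition assembly.

test_that("face aggregation takes the per-frame maximum and flags no-face frames", {
    arr <- array(NA_real_, dim = c(3, 2, 2))
    arr[1, , 1] <- c(0.2, 0.7); arr[1, , 2] <- c(0.1, 0.05)
    arr[2, 1, ] <- c(0.4, 0.3)               # single face
    # frame 3: no faces at all
    out <- aggregateFaces(arr, feature_names = c("joy", "fear"))
    expect_equal(out[1, ], c(0.7, 0.1))
    expect_equal(out[2, ], c(0.4, 0.3))
    expect_equal(out[3, ], c(0, 0))
    expect_equal(attr(out, "no_face"), c(FALSE, FALSE, TRUE))

    arr[1, 1, 1] <- 1.4
    expect_error(aggregateFaces(arr, c("joy", "fear")), "\\[0, 1\\]")

    df <- data.frame(time = c(0, 0, 0.04), face_id = c(1, 2, 1),
                     joy = c(0.2, 0.7, 0.5), fear = c(0.1, 0.05, 0.2))
    got <- aggregateFaces(df, feature_names = c("joy", "fear"))
    expect_equal(unname(got[, "joy"]), c(0.7, 0.5))
})

test_that("bin-average resampling matches closed forms", {
    ev <- data.frame(onset = 0, duration = 30, condition = "speech",
                     block_index = 1)
    fps <- 25
    tt <- seq(0, 30 - 1 / fps, by = 1 / fps)
    raw <- data.frame(time = tt)
    for (nm in tinyVocab()) raw[[nm]] <- 0.5
    ft <- resampleFeatures(raw, ev, feature_names = tinyVocab())
    expect_equal(dim(ft@values), c(1L, 60L, length(tinyVocab())))
    expect_true(all(abs(ft@values - 0.5) < 1e-12))

    # linear ramp: each 0.5 s bin mean equals the ramp midpoint
    raw$guilt <- tt / 30
    ft2 <- resampleFeatures(raw, ev, feature_names = tinyVocab())
    k <- seq_len(60)
    analytic <- (0.5 * (k - 1) + mean(seq(0, 0.48, by = 0.04))) / 30
    expect_lt(max(abs(ft2@values[1, , "guilt"] - analytic)), 1 / 50)

    # an empty bin carries the previous value and is flagged
    raw2 <- raw[raw$time < 10 | raw$time >= 10.5, ]
    ft3 <- resampleFeatures(raw2, ev, feature_names = tinyVocab())
    expect_equal(attr(ft3, "filled"), 1L)
    expect_equal(ft3@values[1, 21, "guilt"], ft3@values[1, 20, "guilt"])

    # a block with no frames at all is an error
    ev2 <- rbind(ev, data.frame(onset = 40, duration = 30,
                                condition = "music", block_index = 2))
    expect_error(resampleFeatures(raw, ev2, feature_names = tinyVocab()),
                 "block 2")
})

test_that("the lagged design has the documented shape and shift structure", {
    ft <- simulateFeatures(1, seed = 2, fs = 2, duration = 30,
                           face_free_blocks = integer())
    des <- buildDesignMatrix(ft, c(0, 0.5, 1))
    expect_equal(dim(des@X), c(60L, 144L))
    expect_equal(des@colLabels$feature[1:3], rep(emotionVocabulary()[1], 3))
    expect_equal(des@colLabels$lag[1:3], c(0, 0.5, 1))

    # impulse at bin 10 of one feature appears at rows 10/11/12 of its
    # three lag columns, nowhere else
    vals <- array(0, dim = c(1, 60, 2), dimnames = list(NULL, NULL,
                                                        c("joy", "fear")))
    vals[1, 10, "joy"] <- 1
    imp <- new("FeatureTimecourse", values = vals, fs = 2,
               blockMeta = data.frame(block_index = 1,
                                      condition = "speech"))
    X <- buildDesignMatrix(imp, c(0, 0.5, 1))@X
    expect_equal(which(X[, 1] == 1), 10L)
    expect_equal(which(X[, 2] == 1), 11L)
    expect_equal(which(X[, 3] == 1), 12L)
    expect_equal(sum(X), 3)

    # constant feature: lagged columns constant except zero-padded heads
    vals[1, , "fear"] <- 0.3
    cst <- new("FeatureTimecourse", values = vals, fs = 2,
               blockMeta = imp@blockMeta)
    Xc <- buildDesignMatrix(cst, c(0, 0.5, 1))@X
    expect_true(all(Xc[, 4] == 0.3))
    expect_equal(Xc[1, 5], 0)
    expect_true(all(Xc[-1, 5] == 0.3))
    expect_equal(Xc[1:2, 6], c(0, 0))

    expect_error(buildDesignMatrix(imp, 0.3), "multiple")
})

test_that("response binning averages half-open windows exactly", {
    fs <- 400
    n_margin <- round(0.2 * fs)
    n <- n_margin + 30 * fs
    dat <- array(0, dim = c(1, 1, n))
    dat[1, 1, ] <- 5
    ep <- new("HFBEpochs", data = dat, fs = fs,
              blockMeta = data.frame(block_index = 1,
                                     condition = "speech", onset = 0),
              channels = data.frame(), margin = 0.2, stage = "normalized")
    br <- binResponse(ep, 0.5)
    expect_equal(dim(br@y), c(60L, 1L))
    expect_true(all(br@y == 5))

    # sawtooth within one bin: bin mean equals the analytic average
    saw <- ep
    saw@data[1, 1, n_margin + 1:200] <- seq_len(200)
    br2 <- binResponse(saw, 0.5)
    expect_equal(br2@y[1, 1], mean(seq_len(200)), tolerance = 1e-9)
    expect_equal(br2@y[2, 1], 5)

    expect_error(binResponse(ep, 1 / 3), "integer")
})

test_that("condition assembly keeps aligned rows in stimulus order", {
    cfg <- tinyConfig()
    ft <- simulateFeatures(13, seed = 4, feature_names = tinyVocab())
    ret <- ft
    keep <- ft@blockMeta$block_index != 9
    ret@values <- ft@values[keep, , , drop = FALSE]
    ret@blockMeta <- ft@blockMeta[keep, , drop = FALSE]
    tr <- groundTruth(tinyVocab(), cfg@lags, seed = 5)
    resp <- simulateResponse(ret, tr, seed = 6, n_contacts = 2)
    des <- buildDesignMatrix(ret, cfg@lags)

    sp <- assembleCondition(des, resp, "speech")
    expect_equal(nrow(sp$design@X), 360L)    # 6 speech blocks x 60 bins
    mu <- assembleCondition(des, resp, "music")
    expect_equal(nrow(mu$design@X), 360L)    # 7 music blocks - excluded
    expect_identical(sp$design@rowMeta[c("block_index", "bin")],
                     sp$response@rowMeta[c("block_index", "bin")])

    only9 <- resp
    expect_error(assembleCondition(des, resp, "silence"), "no retained")
})

test_that("changing one feature bin touches only rows t..t+maxlag", {
    ft <- gridFeatures(n_blocks = 2, n_bins = 20)
    X1 <- buildDesignMatrix(ft, c(0, 0.5, 1))@X
    ft2 <- ft
    ft2@values[2, 7, 3] <- 0.987
    X2 <- buildDesignMatrix(ft2, c(0, 0.5, 1))@X
    changed <- which(rowSums(X1 != X2) > 0)
    expect_equal(changed, 20 + c(7L, 8L, 9L))
})
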