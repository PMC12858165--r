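# Ridge solver, cross-validation, contact concatenation, shared-alpha
# selection and the study-level loop.

test_that("ridge limits: infinite penalty and orthonormal OLS", {
    set.seed(1)
    X <- matrix(rnorm(200), 50)
    y <- rnorm(50)
    big <- ridgeSolve(X, y, 1e12)
    expect_lt(sqrt(sum(big$weights^2)), 1e-6)
    expect_equal(big$intercept, mean(y), tolerance = 1e-6)

    Q <- qr.Q(qr(scale(matrix(rnorm(100 * 4), 100), scale = FALSE)))
    yq <- rnorm(100)
    ols <- ridgeSolve(Q, yq, 0)
    expect_equal(ols$weights, as.numeric(crossprod(Q, yq - mean(yq))),
                 tolerance = 1e-10)

    expect_error(ridgeSolve(matrix(c(1, NA), 1), 1, 1), "non-finite")
    expect_error(ridgeSolve(X, y, -1), "non-negative")
})

test_that("weight norm shrinks monotonically in alpha", {
    set.seed(2)
    X <- matrix(rnorm(40 * 8), 40)
    y <- rnorm(40)
    norms <- vapply(alphaGrid(),
                    function(a) sqrt(sum(ridgeSolve(X, y, a)$weights^2)),
                    0)
    expect_true(all(diff(norms) <= 1e-12))
})

test_that("cross-validation recovers perfect signal and is null on noise", {
    set.seed(3)
    X <- matrix(rnorm(300 * 6), 300)
    w <- c(2, -1, 0.5, 0, 1, -2)
    fit <- crossvalFit(X, X %*% w + 3, alpha = 1e-6)
    expect_gt(meanR(fit), 0.99)
    expect_equal(length(foldR(fit)), 5L)

    nulls <- vapply(1:100, function(i) {
        set.seed(100 + i)
        Xi <- matrix(rnorm(100 * 5), 100)
        meanR(crossvalFit(Xi, rnorm(100), alpha = 1))
    }, 0)
    expect_lt(abs(mean(nulls)), 0.05)

    # degenerate held-out fold: NaN excluded from the mean with a warning
    yc <- c(rnorm(80), rep(1, 20))
    expect_warning(fitd <- crossvalFit(matrix(rnorm(200), 100), yc,
                                       alpha = 1),
                   "degenerate")
    expect_true(is.nan(foldR(fitd)[5]))
    expect_true(is.finite(meanR(fitd)))
})

test_that("contact concatenation tiles the design per contact", {
    ft <- gridFeatures(n_blocks = 3, n_bins = 20)
    des <- buildDesignMatrix(ft, c(0, 0.5))
    set.seed(4)
    y4 <- matrix(rnorm(60 * 4), 60)
    colnames(y4) <- paste0("c", 1:4)
    resp <- new("BinnedResponse", y = y4, rowMeta = des@rowMeta)
    ds <- concatenateContacts(des, resp)
    expect_equal(nrow(ds$X), 240L)
    expect_equal(ds$n_contacts, 4L)
    expect_equal(ds$X[61:120, ], des@X)      # tiled copy per contact
    expect_equal(ds$y[61:120], y4[, 2])
    expect_equal(ds$base, rep(1:60, 4))

    one <- concatenateContacts(des, new("BinnedResponse",
                                        y = y4[, 1, drop = FALSE],
                                        rowMeta = des@rowMeta))
    expect_identical(one$X, des@X)

    expect_error(concatenateContacts(des, resp, min_contacts = 5),
                 "4 contact")

    # identical contacts: stacking duplicates every row, so the stacked
    # fit at penalty 2*alpha equals the single-contact fit at alpha
    # exactly, and the same-alpha fits agree closely
    same <- new("BinnedResponse", y = cbind(a = y4[, 1], b = y4[, 1]),
                rowMeta = des@rowMeta)
    ds2 <- concatenateContacts(des, same)
    f1 <- crossvalFit(des@X, y4[, 1], 5)
    f2 <- crossvalFit(ds2$X, ds2$y, 10, base = ds2$base)
    expect_equal(f2@weights, f1@weights, tolerance = 1e-9)
    expect_equal(meanR(f2), meanR(f1), tolerance = 1e-9)
    f2b <- crossvalFit(ds2$X, ds2$y, 5, base = ds2$base)
    expect_equal(meanR(f2b), meanR(f1), tolerance = 0.01)
})

test_that("shared alpha maximizes the average cross-validated accuracy", {
    grid <- alphaGrid()
    expect_equal(grid[c(1, 20)], c(10, 10000))
    expect_true(all(diff(grid) > 0))

    # dataset A: strong clean signal (prefers small alpha);
    # dataset B: weak signal in noise (prefers heavy shrinkage)
    set.seed(5)
    XA <- matrix(rnorm(200 * 10), 200)
    dsA <- list(X = XA, y = as.numeric(XA %*% rnorm(10) + 0.1 * rnorm(200)),
                base = 1:200)
    XB <- matrix(rnorm(200 * 10), 200)
    dsB <- list(X = XB, y = as.numeric(XB %*% rnorm(10, sd = 0.05) +
                                       3 * rnorm(200)),
                base = 1:200)
    single <- selectSharedAlpha(list(dsA), grid)
    curveA <- attr(single, "curve")
    expect_equal(as.numeric(single), grid[which.max(curveA)])

    shared <- selectSharedAlpha(list(dsA, dsB), grid)
    cA <- attr(selectSharedAlpha(list(dsA), grid), "curve")
    cB <- attr(selectSharedAlpha(list(dsB), grid), "curve")
    expect_equal(as.numeric(shared), grid[which.max((cA + cB) / 2)])

    expect_error(selectSharedAlpha(list()), "empty")
})

test_that("the study loop fits every qualifying subject/region/condition", {
    cfg <- tinyConfig()
    st <- simulateCohort(ages = c(8, 25, 40), seed = 6,
                         regions = c("DLPFC", "pSTC"), n_contacts = 4,
                         snr = 2, slope_features = character(0),
                         config = cfg)
    fits <- fitAll(st, cfg)
    expect_length(fits, 12L)                 # 3 subjects x 2 x 2
    expect_true(all(vapply(fits, function(f) f@alpha, 0) ==
                    attr(fits, "alpha")))
    expect_true(all(vapply(fits, function(f) f@nRows, 0) == 360 * 4))

    st$responses[["s01"]][["DLPFC"]] <- NULL
    fits2 <- fitAll(st, cfg)
    expect_length(fits2, 10L)                # pSTC-only subject gives 2

    cfg5 <- tinyConfig(min_contacts = 5)
    expect_message(expect_error(fitAll(st, cfg5), "no .* cell"),
                   "contact")
})

test_that("binned-level fits recover the true weight profile", {
    cfg <- pipelineConfig()
    ft <- simulateFeatures(seed = 1)
    ret <- hfbEncode:::retainBlocks(ft, 9)
    tr <- groundTruth(seed = 101, snr = 1)   # feature-driven share 50%
    resp <- simulateResponse(ret, tr, seed = 201, n_contacts = 1)
    des <- buildDesignMatrix(ret, cfg@lags)
    ds <- concatenateContacts(des, resp)     # 720 stacked rows
    expect_equal(nrow(ds$X), 720L)
    a <- as.numeric(selectSharedAlpha(list(ds), cfg@alpha_grid))
    fit <- crossvalFit(ds$X, ds$y, a, base = ds$base)
    rec <- cor(colMeans(abs(fit@weights)),
               abs(hfbEncode:::vecWeights(tr$weights)))
    expect_gt(rec, 0.8)
})
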