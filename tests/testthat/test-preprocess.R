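# Signal chain: notch, common average reference, band amplitude, epoching,
# downsampling, sqrt, baseline z-score, and the chain's invariances.

test_that("notch removes the line frequency and spares the passband", {
    rec50 <- toneRecording(50, dur = 4)
    out50 <- notchFilter(rec50, 50)
    i <- 2049:6144                       # exclude 1 s of edges
    expect_lt(sqrt(mean(out50@data[i, 1]^2)),
              0.1 * sqrt(mean(rec50@data[i, 1]^2)))

    rec125 <- toneRecording(125, dur = 4)
    out125 <- notchFilter(rec125, 50)
    expect_equal(sqrt(mean(out125@data[i, 1]^2)),
                 sqrt(mean(rec125@data[i, 1]^2)), tolerance = 0.02)

    expect_error(notchFilter(toneRecording(10, fs = 90), 50), "Nyquist")
})

test_that("notch dips the white-noise spectrum only around 50 Hz", {
    set.seed(11)
    fs <- 1024
    x <- rnorm(fs * 8)
    rec <- new("IeegRecording", data = cbind(ch1 = x), fs = fs,
               channels = data.frame(name = "ch1", region = "other",
                                     hemisphere = "L", status = "good"))
    out <- notchFilter(rec, 50)
    pgram <- function(v, spans) spec.pgram(ts(v, frequency = fs),
                                           spans = spans, plot = FALSE,
                                           taper = 0)
    # narrow smoothing resolves the dip; broad smoothing judges flatness
    f0 <- pgram(rec@data[, 1], 7); f1 <- pgram(out@data[, 1], 7)
    at50 <- which.min(abs(f0$freq - 50))
    expect_lt(f1$spec[at50] / f0$spec[at50], 0.2)
    s0 <- pgram(rec@data[, 1], 31); s1 <- pgram(out@data[, 1], 31)
    away <- which(abs(s0$freq - 50) > 10 & s0$freq > 5 & s0$freq < 400)
    ratio <- s1$spec[away] / s0$spec[away]
    expect_gt(min(ratio), 0.75)
    expect_lt(max(ratio), 1.25)
})

test_that("common average reference subtracts the good-channel mean", {
    t <- seq(0, 1, by = 1 / 512)
    x <- sin(2 * pi * 7 * t)
    same <- new("IeegRecording",
                data = cbind(a = x, b = x, c = x), fs = 512,
                channels = data.frame(name = c("a", "b", "c"),
                                      region = "other", hemisphere = "L",
                                      status = "good"))
    expect_equal(max(abs(commonAverageReference(same)@data)), 0)

    pair <- new("IeegRecording", data = cbind(a = x, b = -x), fs = 512,
                channels = same@channels[1:2, ])
    expect_equal(commonAverageReference(pair)@data, pair@data)

    set.seed(4)
    five <- matrix(rnorm(512 * 5), ncol = 5)
    colnames(five) <- paste0("c", 1:5)
    ch <- data.frame(name = colnames(five), region = "other",
                     hemisphere = "L",
                     status = c("good", "good", "bad", "good", "good"))
    rec <- new("IeegRecording", data = five, fs = 512, channels = ch)
    out <- commonAverageReference(rec)
    good <- ch$status == "good"
    # per-sample mean of good channels is zero after CAR
    expect_lt(max(abs(rowMeans(out@data[, good]))), 1e-12)
    # the bad channel was excluded from the reference but re-referenced
    expect_equal(out@data[, 3], five[, 3] - rowMeans(five[, good]))

    allbad <- rec
    allbad@channels$status <- "bad"
    expect_error(commonAverageReference(allbad), "good channels")
})

test_that("band-pass + analytic amplitude recovers tone envelopes", {
    fs <- 2048
    i <- (0.2 * fs):(4.8 * fs)
    inband <- extractHFB(toneRecording(125, amp = 3, dur = 5))
    expect_equal(mean(inband@data[i, 1]), 3, tolerance = 0.02)
    expect_equal(inband@unit, "amplitude")

    outband <- extractHFB(toneRecording(20, amp = 3, dur = 5))
    expect_lt(mean(outband@data[i, 1]), 0.1)

    expect_error(extractHFB(toneRecording(125), band = c(110, 2000)),
                 "Nyquist")
})

test_that("analytic amplitude tracks a known noise-carrier envelope", {
    set.seed(9)
    fs <- 2048
    t <- seq(0, 10 - 1 / fs, by = 1 / fs)
    g <- 1 + 0.8 * sin(2 * pi * 0.3 * t)
    bp <- signal::butter(4, c(110, 140) / (fs / 2), "pass")
    carrier <- signal::filtfilt(bp, rnorm(length(t)))
    rec <- new("IeegRecording",
               data = cbind(ch1 = g * carrier / sd(carrier)), fs = fs,
               channels = data.frame(name = "ch1", region = "other",
                                     hemisphere = "L", status = "good"))
    amp <- extractHFB(rec)@data[, 1]
    # compare at the analysis timescale: 0.5 s bin means suppress the
    # carrier's own stochastic envelope fluctuations
    nb <- floor(length(t) / (0.5 * fs))
    binm <- function(v) colMeans(matrix(v[seq_len(nb * 0.5 * fs)],
                                        nrow = 0.5 * fs))
    i <- 2:(nb - 1)
    expect_gt(cor(binm(amp)[i], binm(g)[i]), 0.9)
})

test_that("epoching keeps retained blocks with a baseline margin", {
    ev <- standardEvents()
    fs <- 512
    n <- ceiling((max(ev$onset) + 31) * fs)
    rec <- new("IeegRecording", data = cbind(ch1 = rep(2, n)), fs = fs,
               channels = data.frame(name = "ch1", region = "other",
                                     hemisphere = "L", status = "good"),
               unit = "amplitude")
    ep <- epochBlocks(rec, ev, excluded_blocks = 9)
    expect_equal(dim(ep@data)[1], 12L)
    expect_false(9 %in% ep@blockMeta$block_index)
    expect_true(all(ep@data == 2))          # constant in, constant out
    expect_equal(dim(ep@data)[3], round(30.2 * fs))

    ev0 <- data.frame(onset = 0, duration = 30, condition = "speech",
                      block_index = 1)
    expect_error(epochBlocks(rec, ev0), "beyond the recording")
})

test_that("downsampling is anti-aliased and sqrt halves a constant's log", {
    ev <- data.frame(onset = 1, duration = 30, condition = "speech",
                     block_index = 1)
    fs <- 2048
    t <- seq(0, 33 - 1 / fs, by = 1 / fs)
    env <- 4 + sin(2 * pi * 0.25 * t)
    rec <- new("IeegRecording", data = cbind(ch1 = env), fs = fs,
               channels = data.frame(name = "ch1", region = "other",
                                     hemisphere = "L", status = "good"),
               unit = "amplitude")
    ep <- epochBlocks(rec, ev)
    dn <- downsampleEpochs(ep, 400)
    expect_equal(dim(dn@data)[3], round(30.2 * 400))
    # values at shared time points match the dense trace within 1%
    t400 <- (seq_len(dim(dn@data)[3]) - 1) / 400 + (1 - 0.2)
    ref <- 4 + sin(2 * pi * 0.25 * t400)
    i <- 200:(length(ref) - 200)
    expect_lt(max(abs(dn@data[1, 1, i] - ref[i])) / 4, 0.01)

    const <- ep
    const@data[] <- 4
    out <- sqrtTransform(downsampleEpochs(const, 400))
    inner <- 200:(dim(out@data)[3] - 200)    # filter edge transients aside
    expect_true(all(abs(out@data[1, 1, inner] - 2) < 1e-6))
    expect_equal(dim(out@data)[3] - round(0.2 * 400), 12000L)

    neg <- const
    neg@data[1, 1, 1] <- -1
    expect_error(sqrtTransform(neg), "negative amplitude")
})

test_that("baseline z-scoring gives exact zero-mean unit-SD baselines", {
    set.seed(21)
    dat <- array(rnorm(3 * 2 * 500, mean = 5, sd = 2), dim = c(3, 2, 500))
    ep <- new("HFBEpochs", data = dat, fs = 400,
              blockMeta = data.frame(block_index = 1:3,
                                     condition = c("music", "speech",
                                                   "music"),
                                     onset = c(0, 31, 62)),
              channels = data.frame(), margin = 0.2, stage = "sqrt")
    nz <- normalizeHFB(ep)
    nm <- round(0.2 * 400)
    for (b in 1:3) for (j in 1:2) {
        bl <- nz@data[b, j, seq_len(nm)]
        expect_lt(abs(mean(bl)), 1e-10)
        expect_lt(abs(sd(bl) - 1), 1e-10)
    }
    flat <- ep
    flat@data[1, 1, 1:80] <- 7
    expect_error(normalizeHFB(flat), "constant baseline")
})

test_that("the full chain is scale-invariant and channel-separable", {
    cfg <- tinyConfig()
    sub <- simulateSubject(seed = 31, n_blocks = 3, n_contacts = 2,
                           level = "raw", config = tinyConfig(
                               excluded_blocks = numeric()))
    ep1 <- preprocessRecording(sub$recording, sub$events,
                               tinyConfig(excluded_blocks = numeric()))
    scaled <- sub$recording
    scaled@data <- scaled@data * 10
    ep10 <- preprocessRecording(scaled, sub$events,
                                tinyConfig(excluded_blocks = numeric()))
    expect_lt(max(abs(ep1@data - ep10@data)), 1e-6)

    # after CAR, processing channels jointly or singly is identical
    car <- commonAverageReference(notchFilter(sub$recording, 50))
    joint <- extractHFB(car)
    single <- car
    single@data <- car@data[, 1, drop = FALSE]
    single@channels <- car@channels[1, , drop = FALSE]
    alone <- extractHFB(single)
    expect_equal(joint@data[, 1], alone@data[, 1], tolerance = 1e-12)
})

test_that("amplitude-threshold flagging marks only outlier channels", {
    set.seed(8)
    n <- 10000
    ok <- rnorm(n)
    spiky <- rnorm(n)
    spiky[sample(n, 300)] <- rnorm(300, sd = 40)
    rec <- new("IeegRecording", data = cbind(a = ok, b = spiky), fs = 1000,
               channels = data.frame(name = c("a", "b"), region = "other",
                                     hemisphere = "L", status = "good"))
    out <- flagBadChannels(rec)
    expect_equal(out@channels$status, c("good", "bad"))
})
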