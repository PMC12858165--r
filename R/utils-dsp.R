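# Small DSP primitives shared by the preprocessing and simulation code.

# Analytic signal via the frequency-domain construction: zero the negative
# frequencies, double the positive ones. x must be a numeric vector.
analyticSignal <- function(x) {
    n <- length(x)
    if (n < 2L) return(complex(real = x, imaginary = 0))
    X <- stats::fft(x)
    h <- numeric(n)
    if (n %% 2L == 0L) {
        h[1L] <- 1
        h[n / 2L + 1L] <- 1
        h[2L:(n / 2L)] <- 2
    } else {
        h[1L] <- 1
        h[2L:((n + 1L) / 2L)] <- 2
    }
    stats::fft(X * h, inverse = TRUE) / n
}

# Second-order IIR notch (biquad) at frequency f0 with quality factor Q,
# the standard design used by scipy.signal.iirnotch / Octave.
designNotch <- function(f0, fs, Q) {
    w0 <- 2 * pi * f0 / fs
    alpha <- sin(w0) / (2 * Q)
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    list(b = b / a[1L], a = a / a[1L])
}

# Zero-phase anti-aliased rate conversion of a vector sampled at fs_from to
# fs_to. An eighth-order Butterworth low-pass at 0.8 x the new Nyquist is
# applied forward-backward, then the trace is read off at the target grid
# (t = 0, 1/fs_to, ...). Upsampling skips the low-pass.
resampleSignal <- function(x, fs_from, fs_to, n_out = NULL) {
    if (is.null(n_out))
        n_out <- max(1L, round(length(x) * fs_to / fs_from))
    t_in <- (seq_along(x) - 1L) / fs_from
    t_out <- (seq_len(n_out) - 1L) / fs_to
    if (fs_to < fs_from) {
        lp <- signal::butter(8, 0.8 * (fs_to / 2) / (fs_from / 2),
                             type = "low")
        x <- signal::filtfilt(lp, x)
    }
    out <- stats::approx(t_in, x, xout = pmin(t_out, t_in[length(t_in)]),
                         rule = 2)$y
    out
}

# Apply a filter forward-backward (zero phase) to every channel of a
# samples x channels matrix.
filtfiltMatrix <- function(filt, data) {
    out <- data
    for (j in seq_len(ncol(data)))
        out[, j] <- signal::filtfilt(filt, data[, j])
    out
}

# 1/f ("pink") noise of length n, unit variance, via FFT spectral shaping.
pinkNoise <- function(n) {
    w <- stats::rnorm(n)
    W <- stats::fft(w)
    f <- c(1, seq_len(n - 1L))
    f <- pmin(f, n - f + 1)          # two-sided frequency index
    W <- W / sqrt(f)
    x <- Re(stats::fft(W, inverse = TRUE) / n)
    as.numeric(scale(x))
}
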