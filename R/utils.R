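# internal helpers

# Evaluate expr with a locally-set RNG seed; the caller's RNG state is
# untouched. seed = NULL means "use the current stream".
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
            inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

# Derive a bounded child seed from a base seed and record indices.
# Stays below 2^31 - 1.
childSeed <- function(seed, ...) {
    idx <- c(...)
    s <- as.double(seed)
    for (i in idx) s <- (s * 69069 + i) %% 2147483629
    as.integer(s) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

isScalarNumber <- function(x) {
    is.numeric(x) && length(x) == 1 && is.finite(x)
}

# Linear-phase FIR applied with group-delay compensation: the output has
# the input's length and no net time shift (edge transients of n/2
# samples at each end are accepted).
applyFirCentered <- function(x, h) {
    n <- length(h)
    stopifnot(n %% 2 == 1)  # odd length = even order, integer delay
    half <- (n - 1L) / 2L
    N <- length(x)
    # power-of-two padded FFT convolution (arbitrary lengths can hit
    # degenerate mixed-radix FFT sizes)
    L <- 2^ceiling(log2(N + n - 1L))
    y <- Re(stats::fft(stats::fft(c(x, numeric(L - N))) *
        stats::fft(c(h, numeric(L - n))), inverse = TRUE)) / L
    y[(half + 1L):(half + N)]
}

# Kaiser-window FIR design (signal::fir1), for a target stopband
# attenuation in dB and a transition band in normalized (Nyquist = 1)
# frequency units.
designKaiserFir <- function(cutoff, type, attenDb, transition) {
    beta <- if (attenDb > 50) 0.1102 * (attenDb - 8.7)
        else if (attenDb >= 21) 0.5842 * (attenDb - 21)^0.4 +
            0.07886 * (attenDb - 21)
        else 0
    n <- ceiling((attenDb - 8) / (2.285 * transition * pi))
    if (n %% 2 == 1) n <- n + 1L  # even order -> odd length, type I
    signal::fir1(n, cutoff, type = type,
        window = signal::kaiser(n + 1, beta))
}
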