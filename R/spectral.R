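# Spectral feature extraction: high-pass filtering, STFT, whole-clip PSD,
# dominant-frequency selection, log-compressed band-power trace, and
# autocorrelation-based periodicity.

ANALYSIS_BAND <- c(350, 4000)  # Hz; covers the fundamentals of interest

#' High-pass filter a clip to remove content below the analysis band
#'
#' Linear-phase FIR high-pass (Kaiser window design) with a 300 Hz
#' stopband edge and a 350 Hz passband edge, ~60 dB stopband attenuation.
#' Applied with group-delay compensation so the output is time-aligned
#' with the input.
#'
#' @param clip an [AudioClip-class]; its sample rate must exceed 700 Hz.
#' @param stopband,passband band edges in Hz.
#' @return the filtered [AudioClip-class].
#' @export
highpass <- function(clip, stopband = 300, passband = 350) {
    stopifnot(is(clip, "AudioClip"))
    fs <- sampleRate(clip)
    if (fs <= 2 * passband)
        stopf("sample rate %g Hz too low for a %g Hz passband edge",
            fs, passband)
    nyq <- fs / 2
    h <- designKaiserFir(cutoff = (stopband + passband) / 2 / nyq,
        type = "high", attenDb = 60,
        transition = (passband - stopband) / nyq)
    AudioClip(applyFirCentered(samples(clip), h), fs)
}

#' Short-time Fourier transform restricted to the analysis band
#'
#' Hamming window of 1024 samples with an overlap of 1008 samples (hop
#' 16); power is the squared magnitude per bin, with bins kept only
#' inside the 350-4000 Hz analysis band.
#'
#' @param clip an [AudioClip-class] with at least `windowLength` samples
#'   (normally the decimated, high-passed signal at 11 025 Hz).
#' @param windowLength analysis window in samples.
#' @param overlap window overlap in samples.
#' @param band analysis band in Hz.
#' @return a [SpectralFrames-class].
#' @export
stft <- function(clip, windowLength = 1024L, overlap = 1008L,
    band = ANALYSIS_BAND) {
    stopifnot(is(clip, "AudioClip"))
    x <- samples(clip)
    fs <- sampleRate(clip)
    windowLength <- as.integer(windowLength)
    hop <- windowLength - as.integer(overlap)
    if (hop < 1) stopf("overlap must be smaller than the window")
    if (length(x) < windowLength)
        stopf("clip too short for STFT: %d < %d samples",
            length(x), windowLength)
    w <- signal::hamming(windowLength)
    starts <- seq(1L, length(x) - windowLength + 1L, by = hop)
    binFreq <- (0:(windowLength %/% 2)) * fs / windowLength
    keep <- which(binFreq >= band[1] & binFreq <= band[2])
    pow <- matrix(0, nrow = length(starts), ncol = length(keep))
    blk <- 2048L  # frames per block, caps the working complex matrix
    for (b in seq(1L, length(starts), by = blk)) {
        ib <- b:min(b + blk - 1L, length(starts))
        idx <- outer(0:(windowLength - 1L), starts[ib] - 1L, "+") + 1L
        X <- stats::mvfft(matrix(x[idx] * w, nrow = windowLength))
        pow[ib, ] <- t(Mod(X[keep, , drop = FALSE])^2)
    }
    new("SpectralFrames",
        frameTimes = (starts - 1 + (windowLength - 1) / 2) / fs,
        binFrequencies = binFreq[keep], power = pow, hop = hop / fs,
        windowDuration = windowLength / fs)
}

#' Whole-clip power spectral density over the analysis band
#'
#' Welch-averaged periodogram (Hamming window, 50% overlap) of the whole
#' clip, computed on a zero-padded grid fine enough for sub-bin peak
#' interpolation and restricted to the 350-4000 Hz band.
#'
#' @param clip an [AudioClip-class] of at least 1024 samples.
#' @param segmentLength Welch segment length in samples (shortened to the
#'   largest power of two that fits short clips).
#' @param oversample zero-padding factor for the frequency grid.
#' @param band analysis band in Hz.
#' @return a [PowerSpectrum-class].
#' @export
fullPSD <- function(clip, segmentLength = 4096L, oversample = 4L,
    band = ANALYSIS_BAND) {
    stopifnot(is(clip, "AudioClip"))
    x <- samples(clip)
    fs <- sampleRate(clip)
    if (length(x) < 1024)
        stopf("clip too short for PSD: %d < 1024 samples", length(x))
    seg <- min(as.integer(segmentLength), 2^floor(log2(length(x))))
    nfft <- seg * as.integer(oversample)
    hop <- seg %/% 2L
    w <- signal::hamming(seg)
    starts <- seq(1L, length(x) - seg + 1L, by = hop)
    acc <- numeric(nfft %/% 2L + 1L)
    for (s in starts) {
        X <- stats::fft(c(x[s:(s + seg - 1L)] * w, numeric(nfft - seg)))
        acc <- acc + Mod(X[1:(nfft %/% 2L + 1L)])^2
    }
    psd <- acc / (length(starts) * sum(w^2) * fs)
    freq <- (0:(nfft %/% 2L)) * fs / nfft
    keep <- freq >= band[1] & freq <= band[2]
    new("PowerSpectrum", frequencies = freq[keep],
        powerDensity = psd[keep])
}

# Interpolated local maxima of a PSD: parabolic interpolation of the
# log-power peak across three bins, then greedy enforcement of a minimum
# separation (strongest peak first). Returns a data.frame sorted by
# descending power.
psdPeaks <- function(psd, minSeparation = 30) {
    p <- psd@powerDensity
    f <- psd@frequencies
    n <- length(p)
    if (n < 3 || max(p) <= 0)
        return(data.frame(frequency = numeric(0), power = numeric(0)))
    i <- which(p[2:(n - 1)] > p[1:(n - 2)] &
        p[2:(n - 1)] >= p[3:n]) + 1L
    if (!length(i))
        return(data.frame(frequency = numeric(0), power = numeric(0)))
    floorp <- max(p) * 1e-15
    lp <- log(p + floorp)
    a <- lp[i - 1L]; b <- lp[i]; cc <- lp[i + 1L]
    denom <- a - 2 * b + cc
    delta <- ifelse(abs(denom) > 0, 0.5 * (a - cc) / denom, 0)
    delta <- pmax(-0.5, pmin(0.5, delta))
    df <- f[2] - f[1]
    pk <- data.frame(frequency = f[i] + delta * df,
        power = exp(b - 0.25 * (a - cc) * delta) - floorp)
    pk <- pk[order(-pk$power), , drop = FALSE]
    keep <- logical(nrow(pk))
    for (j in seq_len(nrow(pk))) {
        if (!any(keep) ||
            all(abs(pk$frequency[keep] - pk$frequency[j]) >=
                minSeparation))
            keep[j] <- TRUE
    }
    pk[keep, , drop = FALSE]
}

#' Select the dominant frequencies of a power spectrum
#'
#' Returns up to `maxCount` interpolated peak frequencies ordered by
#' descending peak power, with accepted peaks separated by at least
#' `minSeparation` Hz. A peak qualifies only if its power reaches
#' `minFraction` of the strongest peak's — the same prominence notion
#' the identification stage applies — so weak modulation sidebands of a
#' dominant tone are not reported as extra alarm frequencies. Fewer
#' than `maxCount` frequencies are returned when fewer peaks qualify;
#' an all-zero PSD yields an empty vector.
#'
#' @param psd a [PowerSpectrum-class].
#' @param maxCount maximum number of frequencies (default 5).
#' @param minSeparation minimum spacing between accepted peaks in Hz.
#' @param minFraction power a peak needs relative to the strongest one.
#' @return numeric vector of frequencies in Hz (descending power order).
#' @export
selectFrequencies <- function(psd, maxCount = 5L, minSeparation = 30,
    minFraction = 0.5) {
    stopifnot(is(psd, "PowerSpectrum"))
    pk <- psdPeaks(psd, minSeparation)
    if (nrow(pk) == 0) return(numeric(0))
    pk <- pk[pk$power >= minFraction * pk$power[1], , drop = FALSE]
    utils::head(pk$frequency, maxCount)
}

#' Frequency of the strongest PSD peak
#'
#' The interpolated frequency of the dominant peak of a power spectrum
#' (`NA` when the spectrum has no peak, e.g. silence).
#'
#' @param psd a [PowerSpectrum-class].
#' @return frequency in Hz.
#' @export
psdMaxFrequency <- function(psd) {
    pk <- psdPeaks(psd)
    if (nrow(pk) == 0) NA_real_ else pk$frequency[1]
}

#' Log-compressed band-power trace of selected frequencies
#'
#' For each STFT frame, sums `log(power + eps)` over the given
#' frequencies (power read at the nearest bin). The floor
#' `eps = epsilonFraction * max(power)` makes the trace bounded below and
#' invariant under amplitude scaling.
#'
#' @param frames a [SpectralFrames-class].
#' @param freqs frequencies of interest in Hz (inside the analysis band).
#' @param epsilonFraction log-compression floor, as a fraction of the
#'   maximum frame power.
#' @return a [BandPowerTrace-class].
#' @export
bandPowerTrace <- function(frames, freqs, epsilonFraction = 1e-2) {
    stopifnot(is(frames, "SpectralFrames"))
    if (length(freqs) < 1)
        stopf("at least one frequency of interest is required")
    bf <- frames@binFrequencies
    if (any(freqs < min(bf) - diff(bf[1:2]) |
            freqs > max(bf) + diff(bf[1:2])))
        stopf("frequencies of interest must lie inside the analysis band")
    cols <- vapply(freqs, function(f) which.min(abs(bf - f)), integer(1))
    mx <- max(frames@power)
    eps <- if (mx > 0) epsilonFraction * mx else .Machine$double.xmin
    vals <- rowSums(log(frames@power[, cols, drop = FALSE] + eps))
    new("BandPowerTrace", times = frames@frameTimes, values = vals,
        hop = frames@hop, windowDuration = frames@windowDuration)
}

#' Normalized autocorrelation of a numeric sequence
#'
#' Mean-removed, zero-lag-normalized, unbiased autocorrelation computed
#' via the Wiener-Khinchin identity (FFT of the zero-padded power
#' spectrum). Equivalent to the direct-sum definition
#' `r[k] = mean_t(x[t] x[t+k]) / mean_t(x[t]^2)` on the mean-removed
#' series, where the lag-k mean runs over the `n - k` available terms.
#' The unbiased scaling matters: the biased estimator's linear taper
#' drags broad peaks toward smaller lags, biasing long repeat intervals
#' by several milliseconds.
#'
#' @param x numeric vector.
#' @return numeric vector of length `length(x)`; element k+1 is the
#'   autocorrelation at lag k (lag 0 is 1 for any non-constant input).
#' @export
autocorrelation <- function(x) {
    x <- as.numeric(x) - mean(x)
    n <- length(x)
    if (n < 2 || all(x == 0)) return(c(1, numeric(n - 1))[seq_len(n)])
    nfft <- 2^ceiling(log2(2L * n))
    X <- stats::fft(c(x, numeric(nfft - n)))
    r <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[1:n]
    r <- r / (n - 0:(n - 1))  # unbiased: average the available terms
    r / r[1]
}

#' Estimate the repeat interval of a band-power trace
#'
#' Computes the mean-removed, zero-lag-normalized autocorrelation of the
#' trace and finds peaks at positive lags with height at least
#' `peakFraction` of the maximum positive-lag autocorrelation value and
#' pairwise distance at least `minPeakDistance`. The first (smallest-lag)
#' qualifying peak is the alarm's shortest repeat interval; its full
#' width at half prominence is the peak width. Lags are searched up to
#' half the trace duration, so any reported period is covered by at
#' least two repeats. Returns `NULL` when no peak qualifies (e.g. a
#' constant trace).
#'
#' @param trace a [BandPowerTrace-class].
#' @param peakFraction autocorrelation peak threshold (default 0.5).
#' @param minPeakDistance minimum peak spacing in seconds (default 0.150).
#' @return a [PeriodicityEstimate-class], or `NULL`.
#' @export
estimatePeriodicity <- function(trace, peakFraction = 0.5,
    minPeakDistance = 0.150) {
    stopifnot(is(trace, "BandPowerTrace"))
    v <- trace@values
    hop <- trace@hop
    n <- length(v)
    if (n < 8 || isTRUE(all.equal(stats::var(v), 0))) return(NULL)
    r <- autocorrelation(v)
    maxLag <- n %/% 2L
    if (maxLag < 2) return(NULL)
    rpos <- r[2:(maxLag + 1L)]  # lags 1..maxLag
    minDist <- max(1L, round(minPeakDistance / hop))
    pk <- tryCatch(
        pracma::findpeaks(rpos,
            minpeakheight = peakFraction * max(rpos),
            minpeakdistance = minDist),
        error = function(e) NULL)
    if (is.null(pk) || nrow(pk) == 0) return(NULL)
    first <- which.min(pk[, 2])
    iPeak <- pk[first, 2]          # lag index within rpos
    height <- pk[first, 1]
    # sub-hop refinement of the peak lag
    lag <- iPeak
    if (iPeak > 1 && iPeak < length(rpos)) {
        a <- rpos[iPeak - 1]; b <- rpos[iPeak]; cc <- rpos[iPeak + 1]
        denom <- a - 2 * b + cc
        if (abs(denom) > 0)
            lag <- iPeak + max(-0.5, min(0.5, 0.5 * (a - cc) / denom))
    }
    periodSec <- lag * hop
    width <- acPeakWidth(rpos, iPeak, minDist) * hop
    if (!is.na(width) && (width <= 0 || width >= periodSec))
        width <- NA_real_
    new("PeriodicityEstimate", period = periodSec,
        peakWidth = if (is.na(width)) numeric(0) else width,
        peakHeight = height)
}

# Full width of an autocorrelation peak at half its prominence, in lag
# units. The prominence base is the higher of the two flanking minima
# (left: lags up to the peak; right: lags from the peak to the search
# limit). NA when the remaining lag range after the peak is shorter
# than `margin` (the base would be truncated and the width
# untrustworthy) or when a half-prominence crossing is not found on a
# clean monotone flank.
acPeakWidth <- function(rpos, iPeak, margin) {
    nr <- length(rpos)
    if (iPeak <= 1 || nr - iPeak < margin) return(NA_real_)
    base <- max(min(rpos[1:iPeak]), min(rpos[iPeak:nr]))
    h <- rpos[iPeak]
    if (h <= base) return(NA_real_)
    level <- h - (h - base) / 2
    # walk down each flank to the half-prominence crossing
    iL <- iPeak
    while (iL > 1 && rpos[iL - 1] >= level && rpos[iL - 1] <= rpos[iL])
        iL <- iL - 1
    if (iL == 1 || rpos[iL - 1] >= level) return(NA_real_)
    xL <- (iL - 1) + (level - rpos[iL - 1]) / (rpos[iL] - rpos[iL - 1])
    iR <- iPeak
    while (iR < nr && rpos[iR + 1] >= level && rpos[iR + 1] <= rpos[iR])
        iR <- iR + 1
    if (iR == nr || rpos[iR + 1] >= level) return(NA_real_)
    xR <- iR + (rpos[iR] - level) / (rpos[iR] - rpos[iR + 1])
    if (xR <= xL) return(NA_real_)
    xR - xL
}

#' Export spectral objects as plain data frames
#'
#' Convenience converters for plotting or CSV export of the intermediate
#' representations (spectrogram, PSD, band-power trace).
#'
#' @param x a [SpectralFrames-class], [PowerSpectrum-class] or
#'   [BandPowerTrace-class].
#' @return a data.frame in long (frames) or column (PSD/trace) form.
#' @export
asDataFrame <- function(x) {
    if (is(x, "SpectralFrames"))
        data.frame(
            time = rep(x@frameTimes, times = length(x@binFrequencies)),
            frequency = rep(x@binFrequencies, each = length(x@frameTimes)),
            power = as.vector(x@power))
    else if (is(x, "PowerSpectrum"))
        data.frame(frequency = x@frequencies, power = x@powerDensity)
    else if (is(x, "BandPowerTrace"))
        data.frame(time = x@times, value = x@values)
    else stopf("no data.frame conversion for class '%s'", class(x)[1])
}
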