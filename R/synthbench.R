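# Synthetic test bench: parametric alarm synthesis from templates,
# seeded pink noise, SNR-mixed corpora and discrimination grids.

#' Synthesize an alarm clip from its template
#'
#' Renders `nBursts` tone bursts, each the sum of equal-amplitude (by
#' default) sinusoids at the template frequencies with raised-cosine
#' on/off ramps, repeating at the template period. Starting phases are
#' randomized per `seed`; phase never affects the extracted features.
#'
#' The default burst duration reproduces the template's autocorrelation
#' peak width where it has one (the width of the first autocorrelation
#' peak corresponds to the tone length within a burst), and is otherwise
#' 40% of the period, capped at 1 s.
#'
#' @param template an [AlarmTemplate-class].
#' @param nBursts number of bursts, >= 2 (default 4 so the trace covers
#'   about three full periods and the first autocorrelation peak has
#'   complete flanks for the width measurement).
#' @param burstDuration tone duration per burst in seconds; must be
#'   < period.
#' @param amplitudes relative weights per frequency (default equal).
#' @param ramp raised-cosine ramp length in seconds; < burstDuration / 2.
#' @param sampleRate output sampling frequency in Hz.
#' @param seed integer controlling phase randomization, or NULL for
#'   zero phases.
#' @param peakAmplitude maximum absolute sample value (default 0.9).
#' @return an [AudioClip-class] of duration
#'   `(nBursts - 1) * period + burstDuration + 0.05` seconds.
#' @examples
#' tpl <- AlarmTemplate("demo", 2713, 0.46, 0.1)
#' clip <- synthesizeAlarm(tpl, nBursts = 4, seed = 7)
#' clipDuration(clip)
#' @export
synthesizeAlarm <- function(template, nBursts = 4L, burstDuration = NULL,
    amplitudes = NULL, ramp = 0.005, sampleRate = 44100, seed = NULL,
    peakAmplitude = 0.9) {
    stopifnot(is(template, "AlarmTemplate"))
    p <- period(template)
    if (is.null(burstDuration))
        burstDuration <- defaultBurstDuration(template)
    if (!isScalarNumber(nBursts) || nBursts < 2)
        stopf("nBursts must be >= 2 (a clip must contain at least two bursts)")
    if (burstDuration <= 0 || burstDuration >= p)
        stopf("burstDuration must be in (0, period)")
    ramp <- min(ramp, burstDuration / 2.5)
    nBursts <- as.integer(nBursts)
    totalDur <- (nBursts - 1) * p + burstDuration + 0.05
    n <- round(totalDur * sampleRate)
    t <- (0:(n - 1)) / sampleRate
    env <- numeric(n)
    nb <- round(burstDuration * sampleRate)
    nr <- max(1L, round(ramp * sampleRate))
    one <- rep(1, nb)
    rampUp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
    one[seq_len(nr)] <- rampUp
    one[nb + 1 - seq_len(nr)] <- rampUp
    for (k in 0:(nBursts - 1)) {
        i0 <- round(k * p * sampleRate)
        idx <- (i0 + 1):min(i0 + nb, n)
        env[idx] <- pmax(env[idx], one[seq_along(idx)])
    }
    fr <- frequencies(template)
    if (is.null(amplitudes)) amplitudes <- rep(1, length(fr))
    if (length(amplitudes) != length(fr))
        stopf("need one amplitude per template frequency")
    phases <- withSeed(seed, stats::runif(length(fr), 0, 2 * pi))
    if (is.null(seed)) phases <- numeric(length(fr))
    x <- numeric(n)
    for (j in seq_along(fr))
        x <- x + amplitudes[j] * sin(2 * pi * fr[j] * t + phases[j])
    x <- x * env
    AudioClip(x / max(abs(x)) * peakAmplitude, sampleRate)
}

# Burst duration that makes the synthesized alarm's measured
# autocorrelation peak width land on the template's stored width (where
# it has one). The analysis pipeline measures the width of the
# log-compressed envelope, which is broadened by the STFT window, so the
# mapping from burst duration to measured width is affine; the constants
# come from the pipeline's window (1024 samples at 11025 Hz) and are
# validated by the synthesis/extraction closure tests.
defaultBurstDuration <- function(template) {
    p <- period(template)
    w <- peakWidth(template)
    if (length(w) == 0) return(min(0.4 * p, 1))
    b <- (w - WIDTH_CAL[1]) / WIDTH_CAL[2]
    min(max(b, 0.01), 0.95 * p)
}

# measured width ~= intercept + slope * burst duration (seconds);
# see defaultBurstDuration.
WIDTH_CAL <- c(0.03, 1.0)

#' Seeded pink noise
#'
#' Generates 1/f ("pink") noise by spectral shaping of seeded white
#' Gaussian noise: the FFT of a white sequence is weighted by
#' 1/sqrt(f) and transformed back, giving an exact -3 dB/octave power
#' slope in expectation. Reproducible per seed.
#'
#' @param duration seconds, > 0.
#' @param sampleRate Hz.
#' @param seed integer RNG seed.
#' @param rmsLevel target RMS amplitude of the output (default 0.1).
#' @return an [AudioClip-class].
#' @examples
#' identical(samples(pinkNoise(1, 8000, seed = 3)),
#'           samples(pinkNoise(1, 8000, seed = 3)))
#' @export
pinkNoise <- function(duration, sampleRate = 44100, seed = 1,
    rmsLevel = 0.1) {
    if (!isScalarNumber(duration) || duration <= 0)
        stopf("duration must be a positive number")
    n <- round(duration * sampleRate)
    L <- 2^ceiling(log2(n))  # shape at a power-of-two length, truncate
    x <- withSeed(seed, stats::rnorm(L))
    X <- stats::fft(x)
    k <- 0:(L - 1)
    f <- sampleRate * pmin(k, L - k) / L  # symmetric -> stays real
    S <- ifelse(f > 0, 1 / sqrt(f), 0)
    y <- Re(stats::fft(X * S, inverse = TRUE))[seq_len(n)] / L
    AudioClip(y / sqrt(mean(y^2)) * rmsLevel, sampleRate)
}

#' Build a labelled SNR-mixed test corpus
#'
#' For each template x replicate x SNR level, synthesizes the alarm
#' (phase seed varies per replicate), mixes it with the chosen noise bed
#' at the requested RMS SNR, and records the ground truth in a manifest.
#' With `noiseKind = "none"` the clean renditions are returned (one per
#' template x replicate).
#'
#' @param db a [TemplateDatabase-class].
#' @param noiseKind `"pink"` (seeded generator), `"file"` (a caller
#'   -supplied bed in `noiseClip`), or `"none"`.
#' @param snrDb numeric vector of SNR levels in dB (ignored for
#'   `"none"`).
#' @param replicates renditions per template (default 5).
#' @param seed master seed; every clip's synthesis and noise seeds are
#'   derived from it.
#' @param sampleRate Hz.
#' @param nBursts bursts per rendition (>= 2).
#' @param noiseClip an [AudioClip-class] noise bed for
#'   `noiseKind = "file"`; must cover the longest rendition.
#' @return a list with `clips` (named list of [AudioClip-class]) and
#'   `manifest` (data.frame: clip_id, template_name, snr_db, noise_kind,
#'   synthesis_seed, noise_seed).
#' @export
makeSnrCorpus <- function(db, noiseKind = c("pink", "file", "none"),
    snrDb = seq(6, -6, by = -1), replicates = 5L, seed = 1L,
    sampleRate = 44100, nBursts = 4L, noiseClip = NULL) {
    stopifnot(is(db, "TemplateDatabase"))
    noiseKind <- match.arg(noiseKind)
    if (noiseKind == "file" && !is(noiseClip, "AudioClip"))
        stopf("noiseKind 'file' requires an AudioClip noise bed")
    if (noiseKind == "none") snrDb <- NA_real_
    clips <- list()
    rows <- list()
    for (ti in seq_len(length(db))) {
        tpl <- db[[ti]]
        for (r in seq_len(replicates)) {
            sseed <- childSeed(seed, 1L, ti, r)
            clean <- synthesizeAlarm(tpl, nBursts = nBursts,
                sampleRate = sampleRate, seed = sseed)
            for (s in snrDb) {
                nseed <- if (is.na(s)) NA_integer_
                    else childSeed(seed, 2L, ti, r, round(10 * s))
                clip <- if (is.na(s)) clean
                else if (noiseKind == "pink")
                    mixAtSnr(clean, pinkNoise(clipDuration(clean),
                        sampleRate, seed = nseed), s)
                else mixAtSnr(clean, noiseClip, s,
                    offset = noiseOffset(noiseClip, clean, nseed))
                id <- sprintf("t%02d_r%d_%s%s", ti, r, noiseKind,
                    if (is.na(s)) "" else sprintf("_snr%+03d", round(s)))
                clips[[id]] <- clip
                rows[[length(rows) + 1L]] <- data.frame(
                    clip_id = id, template_name = templateName(tpl),
                    snr_db = s, noise_kind = noiseKind,
                    synthesis_seed = sseed, noise_seed = nseed,
                    stringsAsFactors = FALSE)
            }
        }
    }
    list(clips = clips, manifest = do.call(rbind, rows))
}

# Seeded noise-bed offset such that the excerpt covers the signal.
noiseOffset <- function(noiseClip, signalClip, seed) {
    slack <- clipDuration(noiseClip) - clipDuration(signalClip)
    if (slack < 0)
        stopf("noise bed shorter than the signal (%.2f s < %.2f s)",
            clipDuration(noiseClip), clipDuration(signalClip))
    withSeed(seed, stats::runif(1, 0, slack))
}

#' Build a discrimination grid of detuned alarm tones
#'
#' For one probe template (a single fundamental frequency), synthesizes
#' one tone per (frequency offset, period offset) pair across the stated
#' sweep — by default +/-7 Hz in 1 Hz steps and +/-50 ms in 10 ms steps
#' around the template — with the true offsets recorded in the manifest.
#'
#' @param template an [AlarmTemplate-class] with exactly one frequency.
#' @param frequencyOffsets Hz offsets (default -7..7 step 1).
#' @param periodOffsetsMs ms offsets (default -50..50 step 10).
#' @param nBursts bursts per tone.
#' @param sampleRate Hz.
#' @param seed master phase seed.
#' @return a list with `clips` and `manifest` (clip_id, template_name,
#'   freq_offset_hz, period_offset_ms, synthesis_seed).
#' @export
makeThresholdGrid <- function(template, frequencyOffsets = -7:7,
    periodOffsetsMs = seq(-50, 50, by = 10), nBursts = 4L,
    sampleRate = 44100, seed = 1L) {
    stopifnot(is(template, "AlarmTemplate"))
    if (length(frequencies(template)) != 1)
        stopf("grid synthesis needs a single-fundamental template")
    burst <- defaultBurstDuration(template)
    if (any(period(template) + periodOffsetsMs / 1000 <= burst))
        stopf("period offsets leave no room for the burst")
    clips <- list()
    rows <- list()
    for (df in frequencyOffsets) for (dpMs in periodOffsetsMs) {
        tpl <- AlarmTemplate(templateName(template),
            frequencies(template) + df,
            period(template) + dpMs / 1000,
            peakWidth(template))
        sseed <- childSeed(seed, 3L, round(10 * df), round(dpMs))
        id <- sprintf("grid_f%+03d_p%+04d", round(df), round(dpMs))
        clips[[id]] <- synthesizeAlarm(tpl, nBursts = nBursts,
            burstDuration = burst, sampleRate = sampleRate, seed = sseed)
        rows[[length(rows) + 1L]] <- data.frame(
            clip_id = id, template_name = templateName(template),
            freq_offset_hz = df, period_offset_ms = dpMs,
            synthesis_seed = sseed, stringsAsFactors = FALSE)
    }
    list(clips = clips, manifest = do.call(rbind, rows))
}

#' Write a corpus to disk as WAV files plus a CSV manifest
#'
#' @param corpus a list with `clips` and `manifest` as produced by
#'   [makeSnrCorpus()] or [makeThresholdGrid()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCorpus <- function(corpus, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(corpus$clips))
        writeWav(corpus$clips[[id]], file.path(dir,
            paste0(id, ".wav")))
    utils::write.csv(corpus$manifest, file.path(dir, "manifest.csv"),
        row.names = FALSE, na = "")
    invisible(dir)
}
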