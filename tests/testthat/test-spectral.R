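test_that("highpass separates the design bands", {
    lo <- highpass(sineClip(100, duration = 1, sampleRate = 11025))
    expect_lt(20 * log10(rms(lo) / (1 / sqrt(2))), -40)
    hi <- highpass(sineClip(1000, duration = 1, sampleRate = 11025))
    expect_lt(abs(20 * log10(rms(hi) / (1 / sqrt(2)))), 1)
    z <- highpass(AudioClip(numeric(11025), 11025))
    expect_equal(max(abs(samples(z))), 0)
    expect_error(highpass(AudioClip(numeric(100), 500)), "too low")
})

test_that("stft frame count, band restriction and tone dominance", {
    clip <- sineClip(2196, duration = 1, sampleRate = 11025)
    fr <- stft(clip)
    expect_equal(nrow(fr@power), floor((11025 - 1024) / 16) + 1)  # 626
    expect_true(all(fr@binFrequencies >= 350 &
        fr@binFrequencies <= 4000))
    expect_equal(diff(fr@frameTimes[1:2]), 16 / 11025)
    # the bin nearest 2196 Hz dominates every frame
    nearest <- which.min(abs(fr@binFrequencies - 2196))
    expect_true(all(apply(fr@power, 1, which.max) == nearest))
    expect_error(stft(AudioClip(numeric(500), 11025)), "too short")
})

test_that("white-noise frames have no spurious dominance", {
    clip <- AudioClip(withr::with_seed(42, rnorm(11025)), 11025)
    fr <- stft(clip)
    tot <- rowSums(fr@power)
    expect_lt(max(tot) / min(tot), 3)
})

test_that("fullPSD locates tones to sub-bin accuracy", {
    clip <- sineClip(2196, duration = 1, sampleRate = 11025)
    psd <- fullPSD(clip)
    expect_equal(psd@frequencies[which.max(psd@powerDensity)], 2196,
        tolerance = 2 / 2196)
    # a triad has local maxima at each component
    n <- 22050
    t <- (0:(n - 1)) / 11025
    triad <- AudioClip(sin(2 * pi * 398 * t) + sin(2 * pi * 1195 * t) +
        sin(2 * pi * 2003 * t), 11025)
    found <- sort(selectFrequencies(fullPSD(triad)))
    expect_equal(found, c(398, 1195, 2003), tolerance = 2 / 398)
    # DC-only input has an empty analysis band
    dc <- AudioClip(rep(0.5, 4096), 11025)
    expect_lt(max(fullPSD(dc)@powerDensity), 1e-6)  # only DC leakage
})

test_that("selectFrequencies returns only qualifying, separated peaks", {
    clip <- sineClip(2196, duration = 1, sampleRate = 11025)
    expect_equal(selectFrequencies(fullPSD(clip)), 2196,
        tolerance = 2 / 2196)
    # seven equal tones >= 50 Hz apart: truncated to the strongest five
    n <- 22050
    t <- (0:(n - 1)) / 11025
    f7 <- seq(600, 600 + 6 * 300, by = 300)
    x <- rowSums(sapply(f7, function(f) sin(2 * pi * f * t)))
    got <- selectFrequencies(fullPSD(AudioClip(x, 11025)))
    expect_length(got, 5)
    expect_true(all(vapply(got, function(g) min(abs(f7 - g)) < 2,
        logical(1))))
    # all-zero PSD -> empty
    zero <- new("PowerSpectrum", frequencies = c(400, 500, 600),
        powerDensity = rep(0, 3))
    expect_length(selectFrequencies(zero), 0)
})

test_that("bandPowerTrace is additive in log domain", {
    clip <- sineClip(1000, duration = 0.6, sampleRate = 11025)
    fr <- stft(clip)
    one <- bandPowerTrace(fr, 1000)
    # constant tone -> constant trace (within scalloping noise, log units)
    expect_lt(diff(range(one@values)), 0.01)
    # duplicated frequency doubles the trace
    two <- bandPowerTrace(fr, c(1000, 1000))
    expect_equal(two@values, 2 * one@values, tolerance = 1e-12)
    expect_error(bandPowerTrace(fr, numeric(0)), "at least one")
    expect_error(bandPowerTrace(fr, 9000), "analysis band")
})

test_that("FFT autocorrelation equals the direct-sum oracle", {
    for (n in c(64, 257, 1000, 2000)) {
        x <- withr::with_seed(n, rnorm(n)) +
            sin(2 * pi * (1:n) / 50)
        r <- autocorrelation(x)
        expect_equal(r, bruteAutocorrelation(x), tolerance = 1e-9)
    }
})

test_that("estimatePeriodicity recovers known repeat intervals", {
    hop <- 16 / 11025
    # square-wave trace of period 0.5 s; oracle = brute-force ACF peak
    periodSamples <- round(0.5 / hop)
    v <- rep(rep(c(1, 0), each = periodSamples / 2), 6)
    pe <- estimatePeriodicity(makeTrace(v))
    expect_equal(period(pe), 0.5, tolerance = 0.002 / 0.5)
    rOracle <- bruteAutocorrelation(v)
    kPeak <- which.max(rOracle[2:(length(v) %/% 2)])
    expect_equal(kPeak * hop, 0.5, tolerance = 0.003 / 0.5)
    # constant trace -> no periodicity, not an error
    expect_null(estimatePeriodicity(makeTrace(rep(3.7, 4000))))
    # Flowtron-style burst train at 44.1 kHz through the full pipeline
    tpl <- AlarmTemplate("probe", 2713, 0.46, 0.1)
    clip <- synthesizeAlarm(tpl, nBursts = 4, seed = 9)
    fr <- stft(highpass(decimateBy(clip, 4)))
    pe2 <- estimatePeriodicity(bandPowerTrace(fr, 2713))
    expect_equal(period(pe2), 0.46, tolerance = 0.005 / 0.46)
})

test_that("features are invariant to amplitude scaling", {
    tpl <- AlarmTemplate("probe", c(786, 2347), 1.05, 0.1)
    clip <- synthesizeAlarm(tpl, nBursts = 4, seed = 3)
    loud <- AudioClip(samples(clip) * 7.3, sampleRate(clip))
    for (c2 in list(clip, loud)) {
        d <- highpass(decimateBy(c2, 4))
        f <- sort(selectFrequencies(fullPSD(d)))
        pe <- estimatePeriodicity(bandPowerTrace(stft(d), f))
        expect_equal(f, c(786, 2347), tolerance = 2 / 786)
        expect_equal(period(pe), 1.05, tolerance = 0.01 / 1.05)
    }
})

test_that("period estimates shift by at most one hop under delay", {
    tpl <- AlarmTemplate("probe", 2713, 0.46, 0.1)
    clip <- synthesizeAlarm(tpl, nBursts = 4, seed = 5)
    delayed <- AudioClip(c(numeric(64 * 20), samples(clip)),
        sampleRate(clip))
    est <- function(cl) {
        d <- highpass(decimateBy(cl, 4))
        period(estimatePeriodicity(bandPowerTrace(stft(d), 2713)))
    }
    expect_lt(abs(est(delayed) - est(clip)), 16 / 11025 + 1e-9)
})

test_that("parameter recovery across the template range in light noise", {
    db <- fixtureDb()
    for (nm in c("Aisys CS2 Ventilator - Critical", "Flowtron SCD Pump",
        "Braun Outlook 400 IV Pump - Alarm",
        "Omnicell Medication Dispensing System")) {
        tpl <- db[[nm]]
        clean <- synthesizeAlarm(tpl, nBursts = 4, seed = 11)
        clip <- mixAtSnr(clean, pinkNoise(clipDuration(clean), 44100,
            seed = 12), 20)
        d <- highpass(decimateBy(clip, 4))
        f <- sort(selectFrequencies(fullPSD(d)))
        expect_equal(f, frequencies(tpl), tolerance = 2 / min(f))
        pe <- estimatePeriodicity(bandPowerTrace(stft(d),
            frequencies(tpl)))
        expect_lt(abs(period(pe) - period(tpl)), 0.010)
    }
})
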