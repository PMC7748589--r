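test_that("frequency prominence gates candidates as specified", {
    db <- fixtureDb()
    th <- detectionThresholds()
    # a pure 2196 Hz tone nominates only the Alaris pump
    psd <- fullPSD(sineClip(2196, duration = 1, sampleRate = 11025))
    cand <- frequencyCandidates(psd, db, th)
    expect_equal(unname(vapply(cand, templateName, "")),
        "Alaris PC 8015 IV Pump")
    # the 398/1195/2003 triad nominates both Aisys alarms
    n <- 22050
    t <- (0:(n - 1)) / 11025
    triad <- AudioClip(sin(2 * pi * 398 * t) + sin(2 * pi * 1195 * t) +
        sin(2 * pi * 2003 * t), 11025)
    cand2 <- sort(unname(vapply(frequencyCandidates(fullPSD(triad), db, th),
        templateName, "")))
    expect_equal(cand2, c("Aisys CS2 Ventilator - Critical",
        "Aisys CS2 Ventilator - Warning"))
    # silence nominates nothing
    silent <- fullPSD(AudioClip(numeric(4096), 11025))
    expect_length(frequencyCandidates(silent, db, th), 0)
    expect_error(frequencyCandidates(psd, TemplateDatabase(list()), th),
        "empty")
})

test_that("periodicity verification applies the 37.5 ms window", {
    db <- fixtureDb()
    flow <- db[["Flowtron SCD Pump"]]
    run <- function(periodOffset) {
        shifted <- AlarmTemplate("probe", 2713, 0.46 + periodOffset,
            peakWidth(flow))
        clip <- synthesizeAlarm(shifted, nBursts = 4,
            burstDuration = 0.07, seed = 31)
        frames <- stft(highpass(decimateBy(clip, 4)))
        verifyCandidate(frames, flow)
    }
    hit <- run(0.030)
    expect_true(isMatch(hit))
    miss <- run(0.050)
    expect_false(isMatch(miss))
    expect_equal(failureStage(miss), "periodicity")
})

test_that("same frequencies, different periods: only the right Aisys", {
    db <- fixtureDb()
    clip <- synthesizeAlarm(db[["Aisys CS2 Ventilator - Critical"]],
        nBursts = 4, seed = 32)
    frames <- stft(highpass(decimateBy(clip, 4)))
    good <- verifyCandidate(frames, db[["Aisys CS2 Ventilator - Critical"]])
    expect_true(isMatch(good))
    bad <- verifyCandidate(frames, db[["Aisys CS2 Ventilator - Warning"]])
    expect_false(isMatch(bad))
    expect_equal(failureStage(bad), "periodicity")
})

test_that("the width stage separates the two Philips alarms", {
    db <- fixtureDb()
    clip <- synthesizeAlarm(db[["Philips Intellivue MP30 Monitor - Medium"]],
        nBursts = 4, seed = 33)
    res <- identifyAlarms(clip, db, all = TRUE)
    df <- matchesToDataFrame(res)
    expect_true(df$is_match[df$template ==
        "Philips Intellivue MP30 Monitor - Medium"])
    warn <- df[df$template == "Philips Intellivue MP30 Monitor - Warning", ]
    if (nrow(warn)) {  # Warning is a candidate (485 Hz prominent) ...
        expect_false(warn$is_match)   # ... but its width disagrees
        expect_equal(warn$failure_stage, "width")
    }
})

test_that("identify finds single and simultaneous alarms", {
    db <- fixtureDb()
    a <- synthesizeAlarm(db[["Alaris PC 8015 IV Pump"]], nBursts = 4,
        seed = 41)
    res <- identifyAlarms(a, db)
    expect_equal(vapply(res, templateName, ""), "Alaris PC 8015 IV Pump")
    # two alarms with disjoint frequencies, digitally summed
    f <- synthesizeAlarm(db[["Flowtron SCD Pump"]], nBursts = 10,
        seed = 42)
    n <- min(length(samples(a)), length(samples(f)))
    # comparable spectral prominence: the short-duty pump's tone is
    # spread over more bins, so it needs ~2x the RMS for its PSD peak
    # to rival the long-duty alarm's (the prominence gate is relative
    # to the loudest in-band component)
    xa <- samples(a)[1:n] / rms(samples(a)[1:n])
    xf <- 2 * samples(f)[1:n] / rms(samples(f)[1:n])
    both <- AudioClip(0.4 * (xa + xf) / max(abs(xa + xf)), 44100)
    found <- sort(vapply(identifyAlarms(both, db), templateName, ""))
    expect_equal(found, c("Alaris PC 8015 IV Pump", "Flowtron SCD Pump"))
})

test_that("silence and short input are handled per contract", {
    db <- fixtureDb()
    expect_length(identifyAlarms(AudioClip(numeric(441000), 44100), db),
        0)
    expect_error(identifyAlarms(AudioClip(numeric(1000), 44100), db),
        "too short")
})

test_that("identification is deterministic and scale invariant", {
    db <- fixtureDb()
    clip <- synthesizeAlarm(db[["GE Carescape B650 Monitor - Critical"]],
        nBursts = 4, seed = 51)
    r1 <- matchesToDataFrame(identifyAlarms(clip, db))
    r2 <- matchesToDataFrame(identifyAlarms(clip, db))
    expect_identical(r1, r2)
    quiet <- AudioClip(samples(clip) * 0.013, 44100)
    r3 <- matchesToDataFrame(identifyAlarms(quiet, db))
    expect_equal(r1$template, r3$template)
})

test_that("enlarging tolerances never removes a match", {
    db <- fixtureDb()
    clip <- synthesizeAlarm(db[["BD Pyxis Medication Station"]],
        nBursts = 4, seed = 52)
    base <- detectionThresholds()
    wide <- detectionThresholds(periodTolerance = 0.075,
        frequencyTolerance = 12)
    m1 <- vapply(identifyAlarms(clip, db, base), templateName, "")
    m2 <- vapply(identifyAlarms(clip, db, wide), templateName, "")
    expect_true(all(m1 %in% m2))
})

test_that("pure pink noise never triggers an identification", {
    db <- fixtureDb()
    hits <- 0L
    for (s in 1:100) {
        noise <- pinkNoise(10, 44100, seed = 7000 + s)
        hits <- hits + length(identifyAlarms(noise, db))
    }
    expect_equal(hits, 0L)
})
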