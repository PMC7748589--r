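# The identification algorithm: frequency prominence gate, then
# periodicity (and, when applicable, peak-width) verification per
# candidate template.

#' Templates whose frequencies are prominent in a power spectrum
#'
#' A template is a candidate iff every one of its frequencies has,
#' within `frequencyTolerance`, an interpolated PSD peak whose power is
#' at least `psdFraction` of the maximum in-band PSD. This is the first
#' stage of the identification algorithm; it produces the list of
#' possible devices whose periodicity is then verified.
#'
#' @param psd a [PowerSpectrum-class] of the unknown clip.
#' @param db a non-empty [TemplateDatabase-class].
#' @param thresholds a [DetectionThresholds-class].
#' @return list of candidate [AlarmTemplate-class] objects (possibly
#'   empty, e.g. for silence).
#' @export
frequencyCandidates <- function(psd, db,
    thresholds = detectionThresholds()) {
    stopifnot(is(psd, "PowerSpectrum"), is(db, "TemplateDatabase"),
        is(thresholds, "DetectionThresholds"))
    if (length(db) == 0) stopf("the template database is empty")
    pk <- psdPeaks(psd)
    maxPsd <- max(psd@powerDensity)
    if (maxPsd <= 0 || nrow(pk) == 0) return(list())
    prominent <- pk[pk$power >= thresholds@psdFraction * maxPsd, ,
        drop = FALSE]
    Filter(function(t) {
        all(vapply(frequencies(t), function(f)
            any(abs(prominent$frequency - f) <=
                thresholds@frequencyTolerance), logical(1)))
    }, db@templates)
}

#' Verify a candidate template's periodicity (and peak width)
#'
#' Builds the log-compressed band-power trace at the template's
#' frequencies, estimates the periodicity from its autocorrelation, and
#' declares a match iff the measured period is within `periodTolerance`
#' of the template's. When the template carries an autocorrelation peak
#' width, the measured width must additionally agree within
#' `widthRelativeTolerance` (relative). `failureStage` records the first
#' failed check.
#'
#' @param frames [SpectralFrames-class] of the unknown clip.
#' @param template a candidate [AlarmTemplate-class].
#' @param thresholds a [DetectionThresholds-class].
#' @param measuredFrequencies optional Hz actually measured in the clip
#'   for the template's frequencies (for reporting).
#' @return a [MatchResult-class].
#' @export
verifyCandidate <- function(frames, template,
    thresholds = detectionThresholds(),
    measuredFrequencies = frequencies(template)) {
    stopifnot(is(frames, "SpectralFrames"), is(template, "AlarmTemplate"))
    trace <- bandPowerTrace(frames, frequencies(template))
    pe <- estimatePeriodicity(trace,
        peakFraction = thresholds@autocorrPeakFraction,
        minPeakDistance = thresholds@minPeakDistance)
    fail <- function(stage, p = numeric(0), w = numeric(0))
        new("MatchResult", templateName = templateName(template),
            matchedFrequencies = measuredFrequencies,
            measuredPeriod = p, measuredPeakWidth = w, isMatch = FALSE,
            failureStage = stage)
    if (is.null(pe)) return(fail("periodicity"))
    if (abs(period(pe) - period(template)) > thresholds@periodTolerance)
        return(fail("periodicity", period(pe), peakWidth(pe)))
    if (length(peakWidth(template))) {
        mw <- peakWidth(pe)
        if (length(mw) == 0 ||
            abs(mw - peakWidth(template)) >
                thresholds@widthRelativeTolerance * peakWidth(template))
            return(fail("width", period(pe), mw))
    }
    new("MatchResult", templateName = templateName(template),
        matchedFrequencies = measuredFrequencies,
        measuredPeriod = period(pe), measuredPeakWidth = peakWidth(pe),
        isMatch = TRUE, failureStage = "none")
}

#' Identify which database alarms are present in a clip
#'
#' The complete identification pipeline: decimate by 4, high-pass,
#' whole-clip PSD and STFT, frequency-prominence gate
#' ([frequencyCandidates()]), then periodicity/width verification
#' ([verifyCandidate()]) for each candidate. All positive matches are
#' returned (two very similar alarms can both match), ordered by the
#' absolute difference between measured and template period.
#' Deterministic for fixed input.
#'
#' @param clip an [AudioClip-class]; must still be at least 1024 samples
#'   long after decimation.
#' @param db a [TemplateDatabase-class].
#' @param thresholds a [DetectionThresholds-class].
#' @param decimation integer decimation factor (default 4).
#' @param all if TRUE, return the [MatchResult-class] of every candidate
#'   (diagnostics); default returns only positive matches.
#' @return list of [MatchResult-class] objects (empty when no alarm is
#'   found, e.g. for silence or pure noise).
#' @examples
#' \donttest{
#' db <- alarmTemplates()
#' clip <- synthesizeAlarm(db[["Flowtron SCD Pump"]], seed = 1)
#' identifyAlarms(clip, db)
#' }
#' @export
identifyAlarms <- function(clip, db, thresholds = detectionThresholds(),
    decimation = 4L, all = FALSE) {
    stopifnot(is(clip, "AudioClip"), is(db, "TemplateDatabase"),
        is(thresholds, "DetectionThresholds"))
    if (length(samples(clip)) / decimation < 1024)
        stopf("clip too short to identify: %d samples before decimation",
            length(samples(clip)))
    d <- highpass(decimateBy(clip, decimation))
    psd <- fullPSD(d)
    cands <- frequencyCandidates(psd, db, thresholds)
    if (length(cands) == 0) return(list())
    frames <- stft(d)
    pk <- psdPeaks(psd)
    results <- lapply(cands, function(t) {
        mf <- vapply(frequencies(t), function(f) {
            d <- abs(pk$frequency - f)
            pk$frequency[which.min(d)]
        }, numeric(1))
        verifyCandidate(frames, t, thresholds, measuredFrequencies = mf)
    })
    if (!all) results <- Filter(isMatch, results)
    dev <- vapply(results, function(r) {
        p <- period(r)
        if (length(p)) abs(p - period(db[[templateName(r)]])) else Inf
    }, numeric(1))
    unname(results[order(dev)])
}

#' Flatten identification results to a data.frame
#'
#' @param results list of [MatchResult-class] from [identifyAlarms()].
#' @return one row per result: template, match flag, failure stage,
#'   measured period/width, matched frequencies (semicolon-separated).
#' @export
matchesToDataFrame <- function(results) {
    data.frame(
        template = vapply(results, templateName, character(1)),
        is_match = vapply(results, isMatch, logical(1)),
        failure_stage = vapply(results, failureStage, character(1)),
        measured_period_s = vapply(results, function(r)
            if (length(period(r))) period(r) else NA_real_, numeric(1)),
        measured_peak_width_s = vapply(results, function(r)
            if (length(r@measuredPeakWidth)) r@measuredPeakWidth
            else NA_real_, numeric(1)),
        matched_frequencies_hz = vapply(results, function(r)
            paste(round(frequencies(r), 1), collapse = ";"),
            character(1)),
        stringsAsFactors = FALSE)
}
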