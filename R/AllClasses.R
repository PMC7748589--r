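#' AudioClip: mono audio samples with a sample rate
#'
#' The universal carrier between pipeline stages: a finite sequence of
#' real-valued amplitude samples (nominal range \[-1, 1\]) at a fixed
#' sampling frequency.
#'
#' @slot samples numeric vector of amplitudes; all finite, length >= 1.
#' @slot sampleRate samples per second (Hz), > 0.
#'
#' @seealso [readWav()], [synthesizeAlarm()], [pinkNoise()]
#' @export
setClass("AudioClip",
    representation(samples = "numeric", sampleRate = "numeric"))

setValidity("AudioClip", function(object) {
    msg <- character(0)
    if (length(object@sampleRate) != 1 || !is.finite(object@sampleRate) ||
        object@sampleRate <= 0)
        msg <- c(msg, "sampleRate must be a single positive number")
    if (length(object@samples) < 1)
        msg <- c(msg, "samples must have length >= 1")
    if (anyNA(object@samples) || any(!is.finite(object@samples)))
        msg <- c(msg, "all samples must be finite")
    if (length(msg)) msg else TRUE
})

#' Construct an AudioClip
#'
#' @param samples numeric amplitude vector.
#' @param sampleRate sampling frequency in Hz.
#' @return an [AudioClip-class] object.
#' @examples
#' clip <- AudioClip(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), 8000)
#' clipDuration(clip)
#' @export
AudioClip <- function(samples, sampleRate) {
    new("AudioClip", samples = as.numeric(samples),
        sampleRate = as.numeric(sampleRate))
}

#' @rdname accessors
#' @export
setMethod("samples", "AudioClip", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("sampleRate", "AudioClip", function(x) x@sampleRate)

#' @rdname accessors
#' @export
setMethod("clipDuration", "AudioClip",
    function(x) length(x@samples) / x@sampleRate)

setMethod("show", "AudioClip", function(object) {
    cat(sprintf("AudioClip: %d samples @ %g Hz (%.3f s), rms %.4g\n",
        length(object@samples), object@sampleRate,
        length(object@samples) / object@sampleRate, rms(object@samples)))
})

#' SpectralFrames: short-time Fourier power restricted to the analysis band
#'
#' @slot frameTimes seconds at each analysis-window centre; constant hop.
#' @slot binFrequencies Hz, restricted to the analysis band.
#' @slot power non-negative matrix, frames x bins.
#' @slot hop hop between frames in seconds.
#' @slot windowDuration analysis window length in seconds.
#' @export
setClass("SpectralFrames",
    representation(frameTimes = "numeric", binFrequencies = "numeric",
        power = "matrix", hop = "numeric", windowDuration = "numeric"))

setValidity("SpectralFrames", function(object) {
    msg <- character(0)
    if (nrow(object@power) != length(object@frameTimes) ||
        ncol(object@power) != length(object@binFrequencies))
        msg <- c(msg, "power must be frames x bins")
    if (length(object@frameTimes) > 1 &&
        any(diff(object@frameTimes) <= 0))
        msg <- c(msg, "frameTimes must be strictly increasing")
    if (any(!is.finite(object@power)) || any(object@power < 0))
        msg <- c(msg, "power values must be finite and >= 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SpectralFrames", function(object) {
    cat(sprintf(
        "SpectralFrames: %d frames x %d bins, %.1f-%.1f Hz, hop %.3f ms\n",
        nrow(object@power), ncol(object@power),
        min(object@binFrequencies), max(object@binFrequencies),
        1000 * object@hop))
})

#' PowerSpectrum: whole-clip power spectral density over the analysis band
#'
#' @slot frequencies Hz, strictly increasing.
#' @slot powerDensity non-negative power per frequency.
#' @export
setClass("PowerSpectrum",
    representation(frequencies = "numeric", powerDensity = "numeric"))

setValidity("PowerSpectrum", function(object) {
    msg <- character(0)
    if (length(object@frequencies) != length(object@powerDensity))
        msg <- c(msg, "frequencies and powerDensity must match in length")
    if (length(object@frequencies) > 1 && any(diff(object@frequencies) <= 0))
        msg <- c(msg, "frequencies must be strictly increasing")
    if (any(!is.finite(object@powerDensity)) || any(object@powerDensity < 0))
        msg <- c(msg, "powerDensity must be finite and >= 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PowerSpectrum", function(object) {
    i <- which.max(object@powerDensity)
    cat(sprintf("PowerSpectrum: %d points, %.1f-%.1f Hz, argmax %.1f Hz\n",
        length(object@frequencies), min(object@frequencies),
        max(object@frequencies), object@frequencies[i]))
})

#' BandPowerTrace: log-compressed summed power of selected frequencies
#'
#' One value per STFT frame: the sum over the selected frequencies of
#' log(power + epsilon) at the nearest bin.
#'
#' @slot times seconds (frame centres).
#' @slot values dimensionless log units, finite.
#' @slot hop frame hop in seconds.
#' @slot windowDuration STFT window length in seconds (carried along so
#'   that envelope widths can be interpreted against the analysis window).
#' @export
setClass("BandPowerTrace",
    representation(times = "numeric", values = "numeric", hop = "numeric",
        windowDuration = "numeric"))

setValidity("BandPowerTrace", function(object) {
    msg <- character(0)
    if (length(object@times) != length(object@values))
        msg <- c(msg, "times and values must match in length")
    if (any(!is.finite(object@values)))
        msg <- c(msg, "trace values must be finite")
    if (length(msg)) msg else TRUE
})

setMethod("show", "BandPowerTrace", function(object) {
    cat(sprintf("BandPowerTrace: %d frames over %.3f s\n",
        length(object@values), diff(range(object@times))))
})

#' PeriodicityEstimate: first qualifying autocorrelation peak
#'
#' @slot period lag of the first qualifying peak, seconds > 0.
#' @slot peakWidth full width of that peak at half prominence, seconds;
#'   length-0 when not measurable.
#' @slot peakHeight normalized autocorrelation at the peak, in \[-1, 1\].
#' @export
setClass("PeriodicityEstimate",
    representation(period = "numeric", peakWidth = "numeric",
        peakHeight = "numeric"))

setValidity("PeriodicityEstimate", function(object) {
    msg <- character(0)
    if (length(object@period) != 1 || object@period <= 0)
        msg <- c(msg, "period must be a single positive number")
    if (length(object@peakWidth) > 1)
        msg <- c(msg, "peakWidth must be length 0 or 1")
    if (length(object@peakWidth) == 1 &&
        (object@peakWidth <= 0 || object@peakWidth >= object@period))
        msg <- c(msg, "peakWidth must be in (0, period)")
    if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("period", "PeriodicityEstimate", function(x) x@period)

#' @rdname accessors
#' @export
setMethod("peakWidth", "PeriodicityEstimate", function(x) x@peakWidth)

setMethod("show", "PeriodicityEstimate", function(object) {
    w <- if (length(object@peakWidth))
        sprintf(", width %.3f s", object@peakWidth) else ""
    cat(sprintf("PeriodicityEstimate: period %.4f s (height %.3f%s)\n",
        object@period, object@peakHeight, w))
})

#' AlarmTemplate: the spectral/temporal signature of one alarm sound
#'
#' Up to five characteristic frequencies, a repeat period, and an optional
#' autocorrelation peak width. Each alarm is thus characterized by between
#' two and seven numbers.
#'
#' @slot name device/alarm label.
#' @slot frequencies 1-5 strictly increasing values in Hz, inside the
#'   350-4000 Hz analysis band.
#' @slot period repeat interval in seconds, > 0.
#' @slot peakWidth autocorrelation peak width in seconds (length-0 when
#'   not applicable); when present, < period.
#' @seealso [alarmTemplates()], [extractTemplate()]
#' @export
setClass("AlarmTemplate",
    representation(name = "character", frequencies = "numeric",
        period = "numeric", peakWidth = "numeric"))

setValidity("AlarmTemplate", function(object) {
    msg <- character(0)
    if (length(object@name) != 1 || !nzchar(object@name))
        msg <- c(msg, "name must be a single non-empty string")
    nf <- length(object@frequencies)
    if (nf < 1 || nf > 5)
        msg <- c(msg, "between 1 and 5 frequencies required")
    if (nf > 1 && any(diff(object@frequencies) <= 0))
        msg <- c(msg, "frequencies must be strictly increasing (no duplicates)")
    if (any(object@frequencies < 350) || any(object@frequencies > 4000))
        msg <- c(msg, "frequencies must lie in the 350-4000 Hz analysis band")
    if (length(object@period) != 1 || object@period <= 0)
        msg <- c(msg, "period must be a single positive number")
    if (length(object@peakWidth) > 1)
        msg <- c(msg, "peakWidth must be length 0 or 1")
    if (length(object@peakWidth) == 1 &&
        (object@peakWidth <= 0 || object@peakWidth >= object@period))
        msg <- c(msg, "peakWidth must be in (0, period)")
    if (length(msg)) msg else TRUE
})

#' Construct an AlarmTemplate
#'
#' @param name alarm label (unique within a database).
#' @param frequencies characteristic frequencies in Hz (1-5 values).
#' @param period burst repeat interval in seconds.
#' @param peakWidth optional autocorrelation peak width in seconds.
#' @return an [AlarmTemplate-class] object.
#' @examples
#' AlarmTemplate("Flowtron SCD Pump", 2713, 0.46, 0.1)
#' @export
AlarmTemplate <- function(name, frequencies, period, peakWidth = numeric(0)) {
    new("AlarmTemplate", name = as.character(name),
        frequencies = sort(as.numeric(frequencies)),
        period = as.numeric(period),
        peakWidth = as.numeric(peakWidth[!is.na(peakWidth)]))
}

#' @rdname accessors
#' @export
setMethod("templateName", "AlarmTemplate", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("frequencies", "AlarmTemplate", function(x) x@frequencies)

#' @rdname accessors
#' @export
setMethod("period", "AlarmTemplate", function(x) x@period)

#' @rdname accessors
#' @export
setMethod("peakWidth", "AlarmTemplate", function(x) x@peakWidth)

setMethod("show", "AlarmTemplate", function(object) {
    w <- if (length(object@peakWidth))
        sprintf(", width %.3g s", object@peakWidth) else ""
    cat(sprintf("AlarmTemplate '%s': %s Hz, period %.4g s%s\n", object@name,
        paste(object@frequencies, collapse = "/"), object@period, w))
})

#' TemplateDatabase: a named collection of alarm templates
#'
#' @slot templates list of [AlarmTemplate-class] objects with unique names.
#' @seealso [alarmTemplates()], [loadTemplateDatabase()]
#' @export
setClass("TemplateDatabase", representation(templates = "list"))

setValidity("TemplateDatabase", function(object) {
    msg <- character(0)
    ok <- vapply(object@templates, is, logical(1), class2 = "AlarmTemplate")
    if (!all(ok))
        msg <- c(msg, "all elements must be AlarmTemplate objects")
    else {
        nm <- vapply(object@templates, templateName, character(1))
        if (anyDuplicated(nm))
            msg <- c(msg, sprintf("duplicate template names: %s",
                paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TemplateDatabase
#'
#' @param templates a list of [AlarmTemplate-class] objects.
#' @return a [TemplateDatabase-class] object.
#' @export
TemplateDatabase <- function(templates) {
    if (is(templates, "AlarmTemplate")) templates <- list(templates)
    db <- new("TemplateDatabase", templates = unname(templates))
    names(db@templates) <- vapply(db@templates, templateName, character(1))
    db
}

#' @rdname accessors
#' @export
setMethod("templateNames", "TemplateDatabase",
    function(x) vapply(x@templates, templateName, character(1)))

#' @export
setMethod("length", "TemplateDatabase", function(x) length(x@templates))

#' @export
#' @param i template name or index.
#' @rdname TemplateDatabase-class
setMethod("[[", "TemplateDatabase", function(x, i) x@templates[[i]])

setMethod("show", "TemplateDatabase", function(object) {
    cat(sprintf("TemplateDatabase with %d templates:\n",
        length(object@templates)))
    for (t in object@templates)
        cat("  ", format(templateName(t), width = 42),
            paste(frequencies(t), collapse = "/"), "Hz, ",
            period(t), "s\n")
})

#' DetectionThresholds: tunable decision parameters of the identifier
#'
#' @slot psdFraction fraction of the maximum in-band PSD a template
#'   frequency's peak must reach to count as prominent (default 0.50).
#' @slot periodTolerance maximum |measured - template| period difference
#'   in seconds for a positive match (default 0.0375).
#' @slot frequencyTolerance maximum distance in Hz between a template
#'   frequency and an interpolated PSD peak (default 6).
#' @slot autocorrPeakFraction peak threshold as a fraction of the maximum
#'   positive-lag autocorrelation (default 0.50).
#' @slot minPeakDistance minimum distance between autocorrelation peaks in
#'   seconds (default 0.150).
#' @slot widthRelativeTolerance relative tolerance on the autocorrelation
#'   peak width, applied only when the template carries one (default 0.5).
#' @export
setClass("DetectionThresholds",
    representation(psdFraction = "numeric", periodTolerance = "numeric",
        frequencyTolerance = "numeric", autocorrPeakFraction = "numeric",
        minPeakDistance = "numeric", widthRelativeTolerance = "numeric"))

setValidity("DetectionThresholds", function(object) {
    msg <- character(0)
    frac <- c(object@psdFraction, object@autocorrPeakFraction)
    if (any(frac <= 0) || any(frac > 1))
        msg <- c(msg, "fractions must be in (0, 1]")
    tol <- c(object@periodTolerance, object@frequencyTolerance,
        object@minPeakDistance, object@widthRelativeTolerance)
    if (any(tol <= 0))
        msg <- c(msg, "tolerances must be > 0")
    if (length(msg)) msg else TRUE
})

#' Construct detection thresholds
#'
#' Defaults are the tuned operating point: 50% PSD prominence and a
#' 37.5 ms periodicity tolerance, with a 6 Hz frequency window.
#'
#' @param psdFraction,periodTolerance,frequencyTolerance,autocorrPeakFraction,minPeakDistance,widthRelativeTolerance
#'   see [DetectionThresholds-class].
#' @return a [DetectionThresholds-class] object.
#' @examples
#' detectionThresholds()
#' detectionThresholds(periodTolerance = 0.030)
#' @export
detectionThresholds <- function(psdFraction = 0.50,
    periodTolerance = 0.0375, frequencyTolerance = 6.0,
    autocorrPeakFraction = 0.50, minPeakDistance = 0.150,
    widthRelativeTolerance = 0.5) {
    new("DetectionThresholds", psdFraction = psdFraction,
        periodTolerance = periodTolerance,
        frequencyTolerance = frequencyTolerance,
        autocorrPeakFraction = autocorrPeakFraction,
        minPeakDistance = minPeakDistance,
        widthRelativeTolerance = widthRelativeTolerance)
}

setMethod("show", "DetectionThresholds", function(object) {
    cat(sprintf(paste0("DetectionThresholds: PSD >= %.0f%% of max, ",
        "period +/- %.1f ms, frequency +/- %.1f Hz\n"),
        100 * object@psdFraction, 1000 * object@periodTolerance,
        object@frequencyTolerance))
})

#' MatchResult: the outcome of testing one template against one clip
#'
#' @slot templateName the template tested.
#' @slot matchedFrequencies Hz measured in the clip for the template's
#'   frequencies (length-0 when the frequency stage failed).
#' @slot measuredPeriod seconds (length-0 when no periodicity was found).
#' @slot measuredPeakWidth seconds (length-0 when not measured).
#' @slot isMatch TRUE iff all stages passed.
#' @slot failureStage "none", "frequency", "periodicity" or "width".
#' @export
setClass("MatchResult",
    representation(templateName = "character",
        matchedFrequencies = "numeric", measuredPeriod = "numeric",
        measuredPeakWidth = "numeric", isMatch = "logical",
        failureStage = "character"))

setValidity("MatchResult", function(object) {
    msg <- character(0)
    if (!object@failureStage %in% c("none", "frequency", "periodicity",
        "width"))
        msg <- c(msg, "invalid failureStage")
    if (object@isMatch && object@failureStage != "none")
        msg <- c(msg, "a match must have failureStage 'none'")
    if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("templateName", "MatchResult", function(x) x@templateName)

#' @rdname accessors
#' @export
setMethod("isMatch", "MatchResult", function(x) x@isMatch)

#' @rdname accessors
#' @export
setMethod("failureStage", "MatchResult", function(x) x@failureStage)

#' @rdname accessors
#' @export
setMethod("period", "MatchResult", function(x) x@measuredPeriod)

#' @rdname accessors
#' @export
setMethod("frequencies", "MatchResult", function(x) x@matchedFrequencies)

setMethod("show", "MatchResult", function(object) {
    if (object@isMatch)
        cat(sprintf("MatchResult: '%s' MATCH (period %.4f s)\n",
            object@templateName, object@measuredPeriod))
    else
        cat(sprintf("MatchResult: '%s' no match (failed at %s)\n",
            object@templateName, object@failureStage))
})
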