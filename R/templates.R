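# Template extraction and the template database (JSON/CSV persistence,
# built-in 14-alarm fixture).

#' Extract an alarm template from a clean recording
#'
#' Runs the full feature-extraction pipeline — decimation, high-pass
#' filtering, whole-clip PSD, dominant-frequency selection, band-power
#' trace, autocorrelation periodicity — and packages the result as an
#' [AlarmTemplate-class]. The clip must contain at least two repeats of
#' the alarm with low background noise.
#'
#' The autocorrelation peak width is stored only when it is applicable:
#' the measured width must be below half the period and stable (within
#' 50% relative) between the two halves of the trace; otherwise the
#' template carries no width.
#'
#' @param clip an [AudioClip-class] recording of a single alarm.
#' @param name label for the template.
#' @param decimation integer decimation factor applied first (default 4).
#' @param maxCount maximum number of stored frequencies (default 5).
#' @param minPeakHeight minimum normalized autocorrelation height of the
#'   periodicity peak for the extraction to be trusted; noise-only input
#'   fails this.
#' @return an [AlarmTemplate-class].
#' @examples
#' \donttest{
#' clip <- synthesizeAlarm(alarmTemplates()[["Flowtron SCD Pump"]],
#'     nBursts = 4, seed = 1)
#' extractTemplate(clip, "Flowtron SCD Pump")
#' }
#' @export
extractTemplate <- function(clip, name, decimation = 4L, maxCount = 5L,
    minPeakHeight = 0.15) {
    stopifnot(is(clip, "AudioClip"))
    d <- highpass(decimateBy(clip, decimation))
    psd <- fullPSD(d)
    freqs <- selectFrequencies(psd, maxCount = maxCount)
    if (length(freqs) == 0)
        stopf("extraction failed for '%s': no in-band frequency peaks",
            name)
    frames <- stft(d)
    trace <- bandPowerTrace(frames, freqs)
    pe <- estimatePeriodicity(trace)
    if (is.null(pe) || pe@peakHeight < minPeakHeight)
        stopf("extraction failed for '%s': no stable periodicity found",
            name)
    width <- peakWidth(pe)
    if (length(width)) {
        ok <- width < 0.5 * period(pe) && widthStable(trace, width)
        if (!ok) width <- numeric(0)
    }
    AlarmTemplate(name, sort(freqs), period(pe), width)
}

# Width stability across the two halves of the trace: both halves must
# yield a periodicity peak with a width within 50% (relative) of the
# full-trace width. Halves that are too short to cover two repeats
# simply cannot confirm the width, and it is dropped.
widthStable <- function(trace, width, relTol = 0.5) {
    n <- length(trace@values)
    halves <- list(seq_len(n %/% 2), (n %/% 2 + 1L):n)
    for (idx in halves) {
        half <- new("BandPowerTrace", times = trace@times[idx],
            values = trace@values[idx], hop = trace@hop,
            windowDuration = trace@windowDuration)
        pe <- estimatePeriodicity(half)
        if (is.null(pe) || length(peakWidth(pe)) == 0 ||
            abs(peakWidth(pe) - width) > relTol * width)
            return(FALSE)
    }
    TRUE
}

templateToRecord <- function(t) {
    rec <- list(name = templateName(t), frequencies_hz = frequencies(t),
        period_s = period(t))
    if (length(peakWidth(t))) rec$peak_width_s <- peakWidth(t)
    rec
}

recordToTemplate <- function(rec, where) {
    need <- c("name", "frequencies_hz", "period_s")
    if (!all(need %in% names(rec)))
        stopf("template record %s is missing fields: %s", where,
            paste(setdiff(need, names(rec)), collapse = ", "))
    tryCatch(
        AlarmTemplate(rec$name, unlist(rec$frequencies_hz),
            rec$period_s,
            if (!is.null(rec$peak_width_s)) rec$peak_width_s
            else numeric(0)),
        error = function(e) stopf("invalid template record %s: %s",
            where, conditionMessage(e)))
}

#' Load / save a template database (JSON)
#'
#' The on-disk format is a JSON array of records
#' `{name, frequencies_hz, period_s, peak_width_s?}`. Loading validates
#' every record and rejects duplicate names; save-then-load reproduces
#' the database exactly.
#'
#' @param path path to a template JSON file.
#' @return a [TemplateDatabase-class].
#' @seealso [alarmTemplates()] for the built-in database.
#' @export
loadTemplateDatabase <- function(path) {
    if (!file.exists(path))
        stopf("cannot read template database '%s': no such file", path)
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    if (!is.list(recs) || length(recs) == 0)
        stopf("'%s' contains no template records", path)
    ts <- lapply(seq_along(recs), function(i)
        recordToTemplate(recs[[i]], sprintf("#%d in '%s'", i, path)))
    nm <- vapply(ts, templateName, character(1))
    if (anyDuplicated(nm))
        stopf("duplicate template names in '%s': %s", path,
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
    TemplateDatabase(ts)
}

#' @rdname loadTemplateDatabase
#' @param db a [TemplateDatabase-class].
#' @export
saveTemplateDatabase <- function(db, path) {
    stopifnot(is(db, "TemplateDatabase"))
    recs <- lapply(db@templates, templateToRecord)
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    invisible(path)
}

#' The built-in alarm template database
#'
#' A reference table of 14 alarm sounds from nine medical devices
#' (physiologic monitors, ventilators, infusion pumps, dispensing
#' systems, compression pumps, an electrosurgical unit), each described
#' by its characteristic frequencies, repeat period, and — where
#' applicable — autocorrelation peak width.
#'
#' @return a [TemplateDatabase-class] with 14 templates.
#' @examples
#' db <- alarmTemplates()
#' length(db)
#' db[["Alaris PC 8015 IV Pump"]]
#' @export
alarmTemplates <- function() {
    loadTemplateDatabase(system.file("extdata", "alarm_templates.json",
        package = "alarmid", mustWork = TRUE))
}

#' Import / export a template database as CSV
#'
#' Columns: `name`, `frequencies_hz` (semicolon-separated),
#' `period_s`, `peak_width_s` (may be empty).
#'
#' @param path CSV file path.
#' @return [TemplateDatabase-class] (import) or `path` (export).
#' @export
readTemplateCsv <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("name", "frequencies_hz", "period_s")
    if (!all(need %in% names(df)))
        stopf("template CSV '%s' must have columns: %s", path,
            paste(need, collapse = ", "))
    ts <- lapply(seq_len(nrow(df)), function(i) {
        w <- if ("peak_width_s" %in% names(df) &&
            !is.na(df$peak_width_s[i]) && df$peak_width_s[i] != "")
            as.numeric(df$peak_width_s[i]) else numeric(0)
        tryCatch(
            AlarmTemplate(df$name[i],
                as.numeric(strsplit(as.character(df$frequencies_hz[i]),
                    ";")[[1]]),
                df$period_s[i], w),
            error = function(e) stopf("invalid template row %d of '%s': %s",
                i, path, conditionMessage(e)))
    })
    nm <- vapply(ts, templateName, character(1))
    if (anyDuplicated(nm))
        stopf("duplicate template names in '%s': %s", path,
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
    TemplateDatabase(ts)
}

#' @rdname readTemplateCsv
#' @param db a [TemplateDatabase-class].
#' @export
writeTemplateCsv <- function(db, path) {
    stopifnot(is(db, "TemplateDatabase"))
    df <- data.frame(
        name = templateNames(db),
        frequencies_hz = vapply(db@templates, function(t)
            paste(frequencies(t), collapse = ";"), character(1)),
        period_s = vapply(db@templates, period, numeric(1)),
        peak_width_s = vapply(db@templates, function(t)
            if (length(peakWidth(t))) peakWidth(t) else NA_real_,
            numeric(1)))
    utils::write.csv(df, path, row.names = FALSE, na = "")
    invisible(path)
}
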