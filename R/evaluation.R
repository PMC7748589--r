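# Evaluation: scoring identifications against a manifest, the SNR sweep
# and no-alarm (NPV) protocols, the threshold-performance grid, and the
# threshold tuning grid search.

metricRow <- function(tp, fp, fn, tn) {
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(recall) && !is.na(precision) &&
        (precision + recall) > 0)
        2 * precision * recall / (precision + recall) else NA_real_
    npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
    data.frame(tp = tp, fp = fp, fn = fn, tn = tn, recall = recall,
        precision = precision, f1 = f1, npv = npv)
}

# Normalize identify output to a character vector of matched names.
matchedNames <- function(res) {
    if (is.character(res)) res
    else vapply(Filter(isMatch, res), templateName, character(1))
}

#' Score identification results against a ground-truth manifest
#'
#' Per clip: the true template identified counts as a TP; every
#' identified template that is not present counts as an FP; a missed
#' true template is an FN; a no-alarm clip (manifest `template_name`
#' `NA` or `"NONE"`) with zero identifications is one TN. Metrics that
#' are undefined (zero denominator) are reported as `NA`, never as 0.
#'
#' @param results named list (by `clip_id`) of [identifyAlarms()] output
#'   (or character vectors of matched template names).
#' @param manifest data.frame with `clip_id` and `template_name`;
#'   optional `noise_kind` and `snr_db` columns define strata.
#' @param cumulative if TRUE and several noise kinds are present, append
#'   pooled rows per SNR (noise kind `"Cumulative"`).
#' @return data.frame with one row per stratum plus an `"overall"` row:
#'   counts tp/fp/fn/tn and recall, precision, f1, npv.
#' @export
scoreIdentifications <- function(results, manifest, cumulative = FALSE) {
    need <- c("clip_id", "template_name")
    if (!all(need %in% names(manifest)))
        stopf("manifest must have columns: %s", paste(need, collapse = ", "))
    missing <- setdiff(manifest$clip_id, names(results))
    if (length(missing))
        stopf("no identification result for clips: %s",
            paste(utils::head(missing, 5), collapse = ", "))
    counts <- function(rows) {
        tp <- fp <- fn <- tn <- 0L
        for (i in rows) {
            truth <- manifest$template_name[i]
            found <- matchedNames(results[[manifest$clip_id[i]]])
            if (is.na(truth) || truth == "NONE") {
                fp <- fp + length(found)
                if (length(found) == 0) tn <- tn + 1L
            } else {
                if (truth %in% found) tp <- tp + 1L else fn <- fn + 1L
                fp <- fp + sum(found != truth)
            }
        }
        metricRow(tp, fp, fn, tn)
    }
    noise <- if ("noise_kind" %in% names(manifest))
        manifest$noise_kind else rep("all", nrow(manifest))
    snr <- if ("snr_db" %in% names(manifest))
        manifest$snr_db else rep(NA_real_, nrow(manifest))
    strata <- unique(data.frame(noise_kind = noise, snr_db = snr,
        stringsAsFactors = FALSE))
    out <- do.call(rbind, lapply(seq_len(nrow(strata)), function(j) {
        rows <- which(noise == strata$noise_kind[j] &
            (is.na(snr) == is.na(strata$snr_db[j])) &
            (is.na(snr) | snr == strata$snr_db[j]))
        cbind(strata[j, , drop = FALSE], counts(rows))
    }))
    if (cumulative && length(unique(strata$noise_kind)) > 1) {
        for (s in unique(strata$snr_db)) {
            rows <- which(is.na(snr) == is.na(s) & (is.na(snr) | snr == s))
            out <- rbind(out, cbind(
                data.frame(noise_kind = "Cumulative", snr_db = s),
                counts(rows)))
        }
    }
    overall <- cbind(data.frame(noise_kind = "overall", snr_db = NA_real_),
        counts(seq_len(nrow(manifest))))
    rownames(out) <- NULL
    rbind(out, overall)
}

#' Run the SNR-sweep protocol
#'
#' Builds the labelled corpus ([makeSnrCorpus()]), identifies every clip
#' against the database, and scores per SNR level. The report has the
#' standard benchmark layout: noise, SNR, TP, FP, FN, recall,
#' precision, F1.
#'
#' @param db a [TemplateDatabase-class].
#' @inheritParams makeSnrCorpus
#' @param thresholds a [DetectionThresholds-class].
#' @return data.frame of per-SNR [scoreIdentifications()] rows.
#' @export
runSnrProtocol <- function(db, noiseKind = "pink",
    snrDb = seq(6, -6, by = -1), replicates = 5L, seed = 1L,
    thresholds = detectionThresholds(), sampleRate = 44100,
    nBursts = 4L, noiseClip = NULL) {
    corpus <- makeSnrCorpus(db, noiseKind, snrDb = snrDb,
        replicates = replicates, seed = seed, sampleRate = sampleRate,
        nBursts = nBursts, noiseClip = noiseClip)
    results <- lapply(corpus$clips, identifyAlarms, db = db,
        thresholds = thresholds)
    scoreIdentifications(results, corpus$manifest)
}

#' Run the no-alarm (negative predictive value) protocol
#'
#' Identifies a silent clip and seeded noise-only clips at a range of
#' amplitude levels against the database. Every clip is a true-negative
#' opportunity; any identification converts it into false positives.
#' The manifest must contain no alarms by construction.
#'
#' @param db a [TemplateDatabase-class].
#' @param levelsDb amplitude levels in dB re the generator's reference
#'   RMS (mirrors the 13-step SNR ladder of the sweep protocol).
#' @param replicates noise seeds per level.
#' @param seed master seed.
#' @param duration clip length in seconds (the silent control is 10 s).
#' @param thresholds a [DetectionThresholds-class].
#' @param sampleRate Hz.
#' @return list with `report` (the [scoreIdentifications()] data.frame)
#'   and `nClips`.
#' @export
runNpvProtocol <- function(db, levelsDb = seq(6, -6, by = -1),
    replicates = 4L, seed = 1L, duration = 8,
    thresholds = detectionThresholds(), sampleRate = 44100) {
    clips <- list(silence = AudioClip(numeric(10 * sampleRate),
        sampleRate))
    for (li in seq_along(levelsDb)) for (r in seq_len(replicates)) {
        id <- sprintf("noise_l%+03d_r%d", round(levelsDb[li]), r)
        clips[[id]] <- pinkNoise(duration, sampleRate,
            seed = childSeed(seed, 4L, li, r),
            rmsLevel = 0.1 * 10^(levelsDb[li] / 20))
    }
    manifest <- data.frame(clip_id = names(clips),
        template_name = NA_character_, stringsAsFactors = FALSE)
    results <- lapply(clips, identifyAlarms, db = db,
        thresholds = thresholds)
    list(report = scoreIdentifications(results, manifest),
        nClips = length(clips))
}

#' Run the threshold-performance (discrimination grid) protocol
#'
#' For each probe alarm, generates the grid of detuned tones
#' ([makeThresholdGrid()]), identifies every tone against the full
#' database, and reports per cell whether the probe template was
#' recalled and how many other templates were (falsely) matched.
#'
#' @param db a [TemplateDatabase-class] containing the probes.
#' @param templateNames probe alarm names; the defaults are the
#'   high-fundamental (2713 Hz) and low-fundamental (485 Hz) probes.
#' @param frequencyOffsets,periodOffsetsMs the sweep (defaults as
#'   stated: +/-7 Hz step 1; +/-50 ms step 10).
#' @param nBursts bursts per tone.
#' @param seed master phase seed.
#' @param thresholds a [DetectionThresholds-class].
#' @param sampleRate Hz.
#' @return data.frame: template, freq_offset_hz, period_offset_ms,
#'   detected (logical), n_false_positives.
#' @export
runThresholdPerformance <- function(db,
    templateNames = c("Flowtron SCD Pump",
        "Philips Intellivue MP30 Monitor - Warning"),
    frequencyOffsets = -7:7, periodOffsetsMs = seq(-50, 50, by = 10),
    nBursts = 4L, seed = 1L, thresholds = detectionThresholds(),
    sampleRate = 44100) {
    stopifnot(is(db, "TemplateDatabase"))
    if (!all(templateNames %in% templateNames(db)))
        stopf("probe templates not in database: %s",
            paste(setdiff(templateNames, templateNames(db)),
                collapse = ", "))
    out <- list()
    for (nm in templateNames) {
        grid <- makeThresholdGrid(db[[nm]],
            frequencyOffsets = frequencyOffsets,
            periodOffsetsMs = periodOffsetsMs, nBursts = nBursts,
            sampleRate = sampleRate, seed = seed)
        for (i in seq_len(nrow(grid$manifest))) {
            id <- grid$manifest$clip_id[i]
            found <- matchedNames(identifyAlarms(grid$clips[[id]], db,
                thresholds))
            out[[length(out) + 1L]] <- data.frame(
                template = nm,
                freq_offset_hz = grid$manifest$freq_offset_hz[i],
                period_offset_ms = grid$manifest$period_offset_ms[i],
                detected = nm %in% found,
                n_false_positives = sum(found != nm),
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}

#' Tune the PSD-prominence and periodicity thresholds
#'
#' Grid search over PSD thresholds (40-60% in 5% steps) and periodicity
#' tolerances (30-50 ms in 2.5 ms steps): every combination is scored by
#' its pooled F1 on a labelled training corpus, and the F1-maximal
#' combination is marked selected (ties broken toward the larger period
#' tolerance, then the lower PSD fraction, favoring sensitivity).
#'
#' The expensive clip features (PSD peaks, per-template measured
#' periodicity) do not depend on the tuned parameters and are computed
#' once per clip.
#'
#' @param corpus a labelled corpus (list with `clips`, `manifest`).
#' @param db a [TemplateDatabase-class].
#' @param psdFractions candidate PSD prominence fractions.
#' @param periodTolerances candidate periodicity tolerances in seconds.
#' @param thresholds base [DetectionThresholds-class] supplying the
#'   non-tuned parameters.
#' @param decimation integer decimation factor.
#' @return data.frame: psd_fraction, period_tolerance_s, f1, selected.
#' @export
tuneThresholds <- function(corpus, db,
    psdFractions = seq(0.40, 0.60, by = 0.05),
    periodTolerances = seq(0.030, 0.050, by = 0.0025),
    thresholds = detectionThresholds(), decimation = 4L) {
    if (length(corpus$clips) == 0) stopf("the training corpus is empty")
    feats <- lapply(names(corpus$clips), function(id) {
        d <- highpass(decimateBy(corpus$clips[[id]], decimation))
        psd <- fullPSD(d)
        pk <- psdPeaks(psd)
        maxPsd <- max(psd@powerDensity)
        frames <- NULL
        perTemplate <- lapply(seq_len(length(db)), function(ti) {
            tpl <- db[[ti]]
            # smallest psdFraction at which this template still
            # qualifies: the weakest of its frequencies' best peaks
            qf <- if (maxPsd <= 0 || nrow(pk) == 0) 0 else
                min(vapply(frequencies(tpl), function(f) {
                    near <- abs(pk$frequency - f) <=
                        thresholds@frequencyTolerance
                    if (!any(near)) 0 else max(pk$power[near]) / maxPsd
                }, numeric(1)))
            if (qf < min(psdFractions))
                return(list(qf = qf, period = NA_real_,
                    width = NA_real_))
            if (is.null(frames)) frames <<- stft(d)
            pe <- estimatePeriodicity(
                bandPowerTrace(frames, frequencies(tpl)),
                peakFraction = thresholds@autocorrPeakFraction,
                minPeakDistance = thresholds@minPeakDistance)
            list(qf = qf,
                period = if (is.null(pe)) NA_real_ else period(pe),
                width = if (is.null(pe) || !length(peakWidth(pe)))
                    NA_real_ else peakWidth(pe))
        })
        perTemplate
    })
    names(feats) <- names(corpus$clips)
    grid <- expand.grid(psd_fraction = psdFractions,
        period_tolerance_s = periodTolerances)
    grid$f1 <- vapply(seq_len(nrow(grid)), function(g) {
        frac <- grid$psd_fraction[g]
        tol <- grid$period_tolerance_s[g]
        results <- lapply(names(corpus$clips), function(id) {
            hits <- character(0)
            for (ti in seq_len(length(db))) {
                ft <- feats[[id]][[ti]]
                tpl <- db[[ti]]
                if (ft$qf < frac || is.na(ft$period)) next
                if (abs(ft$period - period(tpl)) > tol) next
                if (length(peakWidth(tpl)) &&
                    (is.na(ft$width) ||
                     abs(ft$width - peakWidth(tpl)) >
                        thresholds@widthRelativeTolerance *
                            peakWidth(tpl))) next
                hits <- c(hits, templateName(tpl))
            }
            hits
        })
        names(results) <- names(corpus$clips)
        rep <- scoreIdentifications(results, corpus$manifest)
        rep$f1[rep$noise_kind == "overall"]
    }, numeric(1))
    best <- order(-grid$f1, -grid$period_tolerance_s,
        grid$psd_fraction)[1]
    grid$selected <- seq_len(nrow(grid)) == best
    grid
}
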