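test_that("scoring implements the TP/FP/FN/TN and metric definitions", {
    manifest <- data.frame(
        clip_id = sprintf("c%02d", 1:10),
        template_name = c(rep("A", 4), rep("B", 3), NA, NA, NA),
        stringsAsFactors = FALSE)
    results <- list(
        c01 = "A", c02 = "A", c03 = "B",        # 1 FP + FN on c03
        c04 = character(0),                      # FN
        c05 = "B", c06 = "B", c07 = c("B", "A"), # extra FP on c07
        c08 = character(0), c09 = character(0),  # TNs
        c10 = "A")                               # FP, not a TN
    rep <- scoreIdentifications(results, manifest)
    ov <- rep[rep$noise_kind == "overall", ]
    expect_equal(ov$tp, 5)
    expect_equal(ov$fp, 3)
    expect_equal(ov$fn, 2)
    expect_equal(ov$tn, 2)
    expect_equal(ov$recall, 5 / 7)
    expect_equal(ov$precision, 5 / 8)
    expect_equal(ov$f1, 2 * (5 / 7) * (5 / 8) / (5 / 7 + 5 / 8))
    expect_equal(ov$npv, 2 / 4)
})

test_that("reference metric examples reproduce", {
    # 70 clips all correctly and solely identified
    manifest <- data.frame(clip_id = sprintf("c%02d", 1:70),
        template_name = rep(sprintf("T%02d", 1:14), each = 5),
        stringsAsFactors = FALSE)
    results <- as.list(manifest$template_name)
    names(results) <- manifest$clip_id
    perfect <- scoreIdentifications(results, manifest)
    ov <- perfect[perfect$noise_kind == "overall", ]
    expect_equal(c(ov$tp, ov$fp, ov$fn), c(70, 0, 0))
    expect_equal(ov$f1, 1.000)
    # TP 67, FP 0, FN 3 -> recall 95.7%, F1 0.978
    miss <- results
    miss[1:3] <- list(character(0), character(0), character(0))
    r2 <- scoreIdentifications(miss, manifest)
    ov2 <- r2[r2$noise_kind == "overall", ]
    expect_equal(round(100 * ov2$recall), 96)
    expect_equal(ov2$precision, 1)
    expect_equal(round(ov2$f1, 3), 0.978)
    # no-alarm-only corpus: NPV defined, precision/recall absent
    m3 <- data.frame(clip_id = c("n1", "n2"),
        template_name = NA_character_, stringsAsFactors = FALSE)
    r3 <- scoreIdentifications(list(n1 = character(0),
        n2 = character(0)), m3)
    ov3 <- r3[r3$noise_kind == "overall", ]
    expect_equal(ov3$npv, 1)
    expect_true(is.na(ov3$recall) && is.na(ov3$precision) &&
        is.na(ov3$f1))
})

test_that("f1 is the harmonic mean wherever defined", {
    manifest <- data.frame(clip_id = sprintf("c%d", 1:6),
        template_name = c("A", "A", "B", "B", NA, NA),
        noise_kind = rep(c("x", "y"), 3),
        snr_db = rep(c(0, -3), each = 3), stringsAsFactors = FALSE)
    results <- list(c1 = "A", c2 = c("A", "B"), c3 = "B",
        c4 = character(0), c5 = character(0), c6 = "A")
    rep <- scoreIdentifications(results, manifest, cumulative = TRUE)
    ok <- !is.na(rep$f1)
    expect_equal(rep$f1[ok],
        2 * rep$precision[ok] * rep$recall[ok] /
            (rep$precision[ok] + rep$recall[ok]),
        tolerance = 1e-12)
    # cumulative rows pool counts across noise kinds at fixed SNR
    cum0 <- rep[rep$noise_kind == "Cumulative" & rep$snr_db == 0, ]
    per0 <- rep[rep$noise_kind %in% c("x", "y") & rep$snr_db == 0, ]
    for (col in c("tp", "fp", "fn", "tn"))
        expect_equal(cum0[[col]], sum(per0[[col]]))
})

test_that("scoring rejects incomplete results", {
    manifest <- data.frame(clip_id = c("a", "b"),
        template_name = c("T", "T"), stringsAsFactors = FALSE)
    expect_error(scoreIdentifications(list(a = "T"), manifest),
        "no identification result")
})

test_that("the NPV protocol rejects corpora containing alarms", {
    # scoring enforces the no-alarm manifest through the TN definition:
    # silence must produce zero identifications
    db <- fixtureDb()
    out <- runNpvProtocol(db, levelsDb = 0, replicates = 1, seed = 1,
        duration = 4, sampleRate = 44100)
    expect_equal(out$report$fp[out$report$noise_kind == "overall"], 0)
    expect_equal(out$report$npv[out$report$noise_kind == "overall"], 1)
})

test_that("threshold tuning searches the stated 5 x 9 grid", {
    db <- TemplateDatabase(list(
        AlarmTemplate("Flowtron SCD Pump", 2713, 0.46, 0.1),
        AlarmTemplate("BD Pyxis Medication Station", 883, 1.1)))
    corpus <- makeSnrCorpus(db, "none", replicates = 2, seed = 3)
    tr <- tuneThresholds(corpus, db)
    expect_equal(nrow(tr), 45)
    expect_setequal(unique(tr$psd_fraction), seq(0.40, 0.60, 0.05))
    expect_setequal(unique(tr$period_tolerance_s),
        seq(0.030, 0.050, 0.0025))
    expect_equal(sum(tr$selected), 1)
    expect_equal(tr$f1[tr$selected], max(tr$f1))
    # the operating point (50%, 37.5 ms) is on the grid
    expect_true(any(abs(tr$psd_fraction - 0.5) < 1e-9 &
        abs(tr$period_tolerance_s - 0.0375) < 1e-9))
    expect_error(tuneThresholds(list(clips = list()), db), "empty")
})
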