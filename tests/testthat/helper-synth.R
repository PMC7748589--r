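# shared fixtures, all generated in code

sineClip <- function(freq, duration = 1, sampleRate = 44100, amp = 1) {
    n <- round(duration * sampleRate)
    AudioClip(amp * sin(2 * pi * freq * (0:(n - 1)) / sampleRate),
        sampleRate)
}

# direct O(n^2) oracle for the unbiased, mean-removed, zero-lag
# normalized autocorrelation
bruteAutocorrelation <- function(x) {
    x <- x - mean(x)
    n <- length(x)
    r <- vapply(0:(n - 1), function(k)
        sum(x[1:(n - k)] * x[(1 + k):n]) / (n - k), numeric(1))
    r / r[1]
}

# a BandPowerTrace built directly from values (unit tests of the
# periodicity estimator that bypass the STFT)
makeTrace <- function(values, hop = 16 / 11025) {
    new("BandPowerTrace", times = (seq_along(values) - 1) * hop,
        values = values, hop = hop, windowDuration = 1024 / 11025)
}

fixtureDb <- function() alarmTemplates()
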