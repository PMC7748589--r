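#' Read a WAV file into an AudioClip
#'
#' Reads RIFF/WAVE audio (PCM 8/16/24/32-bit integer or IEEE float 32/64,
#' including the WAVE_FORMAT_EXTENSIBLE wrapper). Integer samples are
#' rescaled to \[-1, 1\] by dividing by 2^(bits-1); float samples pass
#' through unchanged. Multi-channel audio is reduced to mono by channel
#' averaging.
#'
#' @param path path to a WAV file.
#' @return an [AudioClip-class].
#' @seealso [writeWav()]
#' @export
readWav <- function(path) {
    if (!file.exists(path))
        stopf("cannot read WAV file '%s': no such file", path)
    raw <- readBin(path, "raw", n = file.size(path))
    if (length(raw) < 44 || rawToChar(raw[1:4]) != "RIFF" ||
        rawToChar(raw[9:12]) != "WAVE")
        stopf("'%s' is not a RIFF/WAVE file", path)
    u16 <- function(i) sum(as.integer(raw[i + 0:1]) * c(1, 256))
    u32 <- function(i) sum(as.double(raw[i + 0:3]) * 256^(0:3))
    fmt <- NULL; dataRaw <- NULL
    pos <- 13
    while (pos + 8 <= length(raw)) {
        id <- rawToChar(raw[pos:(pos + 3)])
        size <- u32(pos + 4)
        body <- pos + 8
        if (id == "fmt ") {
            fmt <- list(code = u16(body), channels = u16(body + 2),
                rate = u32(body + 4), bits = u16(body + 14))
            # extensible format: true code is first 2 bytes of SubFormat
            if (fmt$code == 65534 && size >= 40)
                fmt$code <- u16(body + 24)
        } else if (id == "data") {
            dataRaw <- raw[body:min(body + size - 1, length(raw))]
        }
        pos <- body + size + (size %% 2)  # chunks are word-aligned
    }
    if (is.null(fmt) || is.null(dataRaw))
        stopf("'%s' is corrupt: missing fmt/data chunk", path)
    bits <- fmt$bits
    x <- if (fmt$code == 1) {
        if (bits == 8)
            (as.integer(dataRaw) - 128) / 128
        else if (bits == 16)
            readBin(dataRaw, "integer", n = length(dataRaw) / 2, size = 2,
                signed = TRUE, endian = "little") / 32768
        else if (bits == 24) {
            n <- length(dataRaw) %/% 3
            b <- matrix(as.double(dataRaw[seq_len(3 * n)]), nrow = 3)
            v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
            ifelse(v >= 2^23, v - 2^24, v) / 2^23
        } else if (bits == 32) {
            readBin(dataRaw, "integer", n = length(dataRaw) / 4, size = 4,
                signed = TRUE, endian = "little") / 2^31
        } else stopf("unsupported PCM bit depth %d in '%s'", bits, path)
    } else if (fmt$code == 3) {
        readBin(dataRaw, "double", n = length(dataRaw) %/% (bits / 8),
            size = bits / 8, endian = "little")
    } else stopf("unsupported WAV format code %d in '%s'", fmt$code, path)
    if (length(x) == 0)
        stopf("'%s' contains zero-length audio", path)
    if (fmt$channels > 1) {
        n <- length(x) %/% fmt$channels
        x <- colMeans(matrix(x[seq_len(n * fmt$channels)],
            nrow = fmt$channels))
    }
    AudioClip(x, fmt$rate)
}

#' Write an AudioClip to a WAV file
#'
#' @param clip an [AudioClip-class].
#' @param path output path.
#' @param format `"pcm16"` (16-bit integer, default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
writeWav <- function(clip, path, format = c("pcm16", "float32")) {
    stopifnot(is(clip, "AudioClip"))
    format <- match.arg(format)
    x <- samples(clip)
    rate <- round(sampleRate(clip))
    if (format == "pcm16") {
        v <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
        body <- writeBin(v, raw(), size = 2, endian = "little")
        code <- 1L; bits <- 16L
    } else {
        body <- writeBin(as.numeric(x), raw(), size = 4, endian = "little")
        code <- 3L; bits <- 32L
    }
    u32 <- function(v) writeBin(as.integer(v), raw(), size = 4,
        endian = "little")
    u16 <- function(v) writeBin(as.integer(v), raw(), size = 2,
        endian = "little")
    block <- bits / 8L
    hdr <- c(charToRaw("RIFF"), u32(36 + length(body)), charToRaw("WAVE"),
        charToRaw("fmt "), u32(16), u16(code), u16(1),
        u32(rate), u32(rate * block), u16(block), u16(bits),
        charToRaw("data"), u32(length(body)))
    writeBin(c(hdr, body), path)
    invisible(path)
}

#' @rdname rms
#' @export
setMethod("rms", "AudioClip", function(x) sqrt(mean(x@samples^2)))

#' @rdname rms
#' @export
setMethod("rms", "numeric", function(x) {
    if (length(x) < 1) stopf("rms of an empty vector is undefined")
    sqrt(mean(x^2))
})

#' Decimate a clip by an integer factor
#'
#' Applies a linear-phase anti-aliasing low-pass (Kaiser-window FIR,
#' passband edge 0.8x the new Nyquist, >= 70 dB stopband at the new
#' Nyquist) before dropping samples, so content above the new Nyquist is
#' suppressed. The standard preprocessing step is a factor of 4, taking
#' 44.1 kHz material to 11 025 Hz and discarding components above the
#' analysis band.
#'
#' @param clip an [AudioClip-class].
#' @param factor positive integer decimation factor.
#' @return an [AudioClip-class] at `sampleRate(clip) / factor`.
#' @examples
#' clip <- AudioClip(sin(2 * pi * 1000 * (0:44099) / 44100), 44100)
#' decimateBy(clip, 4)
#' @export
decimateBy <- function(clip, factor) {
    stopifnot(is(clip, "AudioClip"))
    if (!isScalarNumber(factor) || factor < 1 || factor != round(factor))
        stopf("decimation factor must be a positive integer")
    factor <- as.integer(factor)
    if (factor == 1L) return(clip)
    if (length(samples(clip)) < factor)
        stopf("clip too short to decimate by %d", factor)
    # transition from 0.8x to 1.0x the new Nyquist, in Nyquist units
    h <- designKaiserFir(cutoff = 0.9 / factor, type = "low",
        attenDb = 70, transition = 0.2 / factor)
    y <- applyFirCentered(samples(clip), h)
    AudioClip(y[seq(1, length(y), by = factor)],
        sampleRate(clip) / factor)
}

#' Mix signal and noise at a prescribed RMS SNR
#'
#' Returns `signal + g * noise` with the gain `g` chosen so that the
#' realized RMS signal-to-noise ratio equals `snrDb`:
#' `g = rms(signal) / rms(noise) * 10^(-snrDb / 20)`. The noise bed is
#' truncated to the signal length starting at `offset` seconds.
#'
#' @param signal,noise [AudioClip-class] objects at equal sample rates;
#'   the noise must cover the signal duration and neither may be silent.
#' @param snrDb target RMS SNR in dB (0 dB = equal RMS).
#' @param offset start of the noise excerpt in seconds (default 0).
#' @return the mixture as an [AudioClip-class].
#' @export
mixAtSnr <- function(signal, noise, snrDb, offset = 0) {
    stopifnot(is(signal, "AudioClip"), is(noise, "AudioClip"))
    if (!isTRUE(all.equal(sampleRate(signal), sampleRate(noise))))
        stopf("sample-rate mismatch: signal %g Hz vs noise %g Hz",
            sampleRate(signal), sampleRate(noise))
    if (!isScalarNumber(snrDb)) stopf("snrDb must be a single number")
    rs <- rms(signal)
    if (rs == 0) stopf("cannot mix: signal is silent")
    i0 <- round(offset * sampleRate(noise))
    n <- length(samples(signal))
    if (i0 + n > length(samples(noise)))
        stopf("noise bed too short: need %d samples from offset %d",
            n, i0)
    nseg <- samples(noise)[(i0 + 1):(i0 + n)]
    rn <- rms(nseg)  # gain from the excerpt actually mixed in
    if (rn == 0) stopf("cannot mix: noise is silent")
    g <- rs / rn * 10^(-snrDb / 20)
    AudioClip(samples(signal) + g * nseg, sampleRate(signal))
}
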