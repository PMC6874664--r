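#' Phase/amplitude band pair
#'
#' Default bands follow the coupling of interest: the phase of the local slow
#' wave at 3--4 Hz and the amplitude envelope of high-frequency activity
#' above 150 Hz (up to the 300 Hz acquisition band edge).
#'
#' @param phaseBand numeric length-2, (low, high) Hz of the phase band.
#' @param ampBand numeric length-2, (low, high) Hz of the amplitude band.
#' @return A list with elements `phaseBand` and `ampBand`.
#' @export
bandPair <- function(phaseBand = c(3, 4), ampBand = c(150, 300)) {
  checkBand <- function(b, nm) {
    if (length(b) != 2L || anyNA(b) || b[1L] <= 0 || b[1L] >= b[2L])
      stopf("'%s' must be (low, high) with 0 < low < high", nm)
  }
  checkBand(phaseBand, "phaseBand"); checkBand(ampBand, "ampBand")
  if (max(phaseBand[1L], ampBand[1L]) < min(phaseBand[2L], ampBand[2L]))
    stopf("phase and amplitude bands must not overlap")
  list(phaseBand = as.numeric(phaseBand), ampBand = as.numeric(ampBand))
}

#' Re-reference a recording to the common average
#'
#' Subtracts, at every sample, the instantaneous mean over the included
#' (artifact-free) channels from each included channel; excluded channels are
#' dropped. After re-referencing, the included channels sum to zero at every
#' sample.
#'
#' @param rec an [EcogRecording-class].
#' @param include channel ids forming the reference (default: all); artifact
#'   channels should be left out.
#' @return A re-referenced [EcogRecording-class] containing only the included
#'   channels.
#' @export
commonAverageReference <- function(rec, include = channelIds(rec)) {
  stopifnot(is(rec, "EcogRecording"))
  miss <- setdiff(include, channelIds(rec))
  if (length(miss))
    stopf("channel(s) not in recording: %s", paste(miss, collapse = ", "))
  if (length(include) < 2L)
    stopf("common average reference needs at least 2 channels (got %d)",
          length(include))
  x <- rec@samples[match(include, channelIds(rec)), , drop = FALSE]
  ref <- colMeans(x)
  ecogRecording(sweep(x, 2L, ref), rec@rate, include, rec@t0)
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-window FIR band-pass applied forward and backward
#' (`signal::filtfilt`) for zero phase distortion, so that coupling phase
#' estimates are unbiased. The filter order spans three cycles of the band's
#' low edge; the output has the length of the input.
#'
#' @param x numeric signal.
#' @param band (low, high) Hz.
#' @param rate sampling rate Hz.
#' @return Filtered signal, same length as `x`.
#' @export
bandpassFilter <- function(x, band, rate) {
  if (length(band) != 2L || anyNA(band) || band[1L] <= 0 ||
      band[1L] >= band[2L])
    stopf("'band' must be (low, high) with 0 < low < high")
  if (band[2L] >= rate / 2)
    stopf("band upper edge %g Hz is at or above Nyquist (%g Hz)",
          band[2L], rate / 2)
  ord <- 2L * ceiling(3 * rate / band[1L] / 2)   # even order, 3 low-edge cycles
  if (length(x) < 3L * ord)
    stopf("signal too short (%d samples) for filter order %d; need >= %d",
          length(x), ord, 3L * ord)
  b <- as.numeric(signal::fir1(ord, band / (rate / 2), type = "pass"))
  as.numeric(signal::filtfilt(b, 1, as.numeric(x)))
}

#' Analytic signal: instantaneous phase and envelope
#'
#' FFT-based Hilbert transform of a real band-limited signal. The phase is
#' the angle of the analytic signal, zero at the band-passed signal's
#' positive peak, in (-pi, pi]; the envelope is its modulus (>= 0).
#'
#' @param x real, band-limited numeric signal.
#' @return List with `phase` (radians) and `envelope` components.
#' @export
analyticSignal <- function(x) {
  n <- length(x)
  if (n == 0L) stopf("cannot take the analytic signal of an empty series")
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2:((n + 1L) / 2L)] <- 2
  }
  z <- stats::fft(stats::fft(as.numeric(x)) * h, inverse = TRUE) / n
  list(phase = Arg(z), envelope = Mod(z))
}

#' Mean-vector-length modulation index
#'
#' The strength of phase-amplitude coupling between an amplitude envelope
#' A(t) and a phase series phi(t), computed as the modulus of the mean
#' complex vector: `MI = |mean(A * exp(1i * phi))|`. MI is non-negative,
#' bounded by `mean(A)`, invariant under a global phase rotation, and scales
#' linearly with envelope gain. With `normalize = TRUE` the
#' envelope-normalised variant `MI / mean(A)` is returned; the unnormalised
#' form is the default (downstream z-scoring absorbs scale).
#'
#' @param phase phase series in radians.
#' @param envelope non-negative envelope series, same length.
#' @param normalize divide by the mean envelope (default `FALSE`).
#' @return Non-negative scalar MI.
#' @examples
#' phi <- seq(-pi, pi, length.out = 1000)
#' modulationIndex(phi, 1 + 0.6 * cos(phi))   # ~ 0.3
#' @export
modulationIndex <- function(phase, envelope, normalize = FALSE) {
  n <- length(phase)
  if (n == 0L) stopf("empty phase/envelope series")
  if (length(envelope) != n)
    stopf("phase (%d) and envelope (%d) lengths differ", n, length(envelope))
  if (any(envelope < 0)) stopf("envelope must be non-negative")
  mi <- Mod(mean(envelope * exp(1i * phase)))
  if (normalize) {
    mA <- mean(envelope)
    mi <- if (mA > 0) mi / mA else 0
  }
  mi
}

#' Block-permutation null distribution of the modulation index
#'
#' Breaks the phase-envelope relationship while preserving the envelope's
#' autocorrelation, by permuting the envelope in contiguous blocks before
#' recomputing MI. Useful to judge whether an observed MI exceeds chance.
#'
#' @param phase,envelope as for [modulationIndex()].
#' @param n number of permutations (default 200).
#' @param block block length in samples (default 1000, i.e. 1 s at 1 kHz).
#' @param normalize passed to [modulationIndex()].
#' @return Numeric vector of `n` null MI values.
#' @export
miPermutationNull <- function(phase, envelope, n = 200, block = 1000,
                              normalize = FALSE) {
  len <- length(envelope)
  nb <- max(1L, floor(len / block))
  idx <- seq_len(nb * block)
  vapply(seq_len(n), function(i) {
    perm <- as.vector(matrix(idx, nrow = block)[, sample.int(nb)])
    modulationIndex(phase[idx], envelope[perm], normalize = normalize)
  }, numeric(1))
}

#' Per-channel modulation index over sleep epochs
#'
#' For each channel of a common-average-referenced recording and each epoch:
#' band-pass both bands, take the analytic phase of the slow band and the
#' analytic envelope of the fast band, trim `edgeTrim` seconds from each
#' epoch edge to suppress filter transients, and compute the
#' mean-vector-length MI. A channel's MI is the arithmetic mean over epochs
#' (by default ten 30-second epochs).
#'
#' @param rec a (re-referenced) [EcogRecording-class].
#' @param epochs an [EpochSpec-class]; all epochs must lie within the
#'   recording.
#' @param bands a [bandPair()] list.
#' @param normalize envelope-normalise MI (see [modulationIndex()]).
#' @param edgeTrim seconds discarded from each epoch edge before MI
#'   (default 1).
#' @return data.frame with one row per channel: `channel_id`, `mi` (epoch
#'   mean) and an `mi_per_epoch` list-column.
#' @export
channelMi <- function(rec, epochs, bands = bandPair(), normalize = FALSE,
                      edgeTrim = 1) {
  stopifnot(is(rec, "EcogRecording"), is(epochs, "EpochSpec"))
  validObject(epochs)
  fs <- rec@rate
  tEnd <- rec@t0 + nSamples(rec) / fs
  bad <- epochs@onsets < rec@t0 - 1e-9 |
         epochs@onsets + epochs@duration > tEnd + 1e-9
  if (any(bad))
    stopf("epoch starting at %g s lies outside the recording [%g, %g] s",
          epochs@onsets[which(bad)[1L]], rec@t0, tEnd)
  if (bands$ampBand[2L] >= fs / 2)
    stopf("amplitude band exceeds Nyquist for rate %g Hz", fs)
  nEp <- length(epochs@onsets)
  epLen <- round(epochs@duration * fs)
  trim <- round(edgeTrim * fs)
  if (2L * trim >= epLen) stopf("'edgeTrim' leaves no samples in the epoch")
  perEpoch <- matrix(0, nrow = nChannels(rec), ncol = nEp)
  for (ch in seq_len(nChannels(rec))) {
    x <- rec@samples[ch, ]
    for (e in seq_len(nEp)) {
      i0 <- round((epochs@onsets[e] - rec@t0) * fs)
      seg <- x[i0 + seq_len(epLen)]
      slow <- bandpassFilter(seg, bands$phaseBand, fs)
      fast <- bandpassFilter(seg, bands$ampBand, fs)
      keep <- (trim + 1L):(epLen - trim)
      phi <- analyticSignal(slow)$phase[keep]
      env <- analyticSignal(fast)$envelope[keep]
      perEpoch[ch, e] <- modulationIndex(phi, env, normalize = normalize)
    }
  }
  out <- data.frame(channel_id = channelIds(rec), mi = rowMeans(perEpoch),
                    stringsAsFactors = FALSE)
  out$mi_per_epoch <- lapply(seq_len(nrow(perEpoch)),
                             function(i) perEpoch[i, ])
  out
}
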