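#' Zero-phase band-pass filter
#'
#' Filters a single signal with a 4th-order Butterworth band-pass applied
#' forward and backward (zero phase, via [signal::filtfilt()]). The output
#' has the same length as the input.
#'
#' @param x numeric vector.
#' @param band numeric length-2 vector `(low_hz, high_hz)`.
#' @param fs sampling rate in Hz.
#' @param order filter order (default 4).
#' @return filtered numeric vector of the same length.
#' @export
#' @examples
#' fs <- 200
#' t <- seq(0, 1, length.out = fs)
#' x <- sin(2 * pi * 10 * t)
#' y <- bandpass(x, c(8, 14), fs) # alpha band passes a 10 Hz tone
bandpass <- function(x, band, fs, order = 4) {
  if (length(band) != 2L || !(0 < band[1] && band[1] < band[2])) {
    stop("band must satisfy 0 < low_hz < high_hz", call. = FALSE)
  }
  if (band[2] >= fs / 2) {
    stop("band edge ", band[2], " Hz is at or above the Nyquist frequency ",
         fs / 2, " Hz", call. = FALSE)
  }
  if (length(x) < 3 * 2 * order) {
    stop("signal too short for a stable order-", order, " band-pass filter",
         call. = FALSE)
  }
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

# internal: squared magnitude response of the order-4 Butterworth band-pass at
# the n FFT bin frequencies (this is the transfer function of forward-backward
# filtering, used by the frequency-domain batch path)
butter_h2 <- function(band, fs, n, order = 4) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  w <- 2 * pi * (0:(n - 1)) / n
  zz <- exp(-1i * w)
  pw <- outer(zz, seq_along(bf$b) - 1, "^")
  H <- (pw %*% bf$b) / (pw %*% bf$a)
  as.numeric(Mod(H)^2)
}

# internal: memoised per-band |H|^2 matrix (n x n_bands)
.h2_cache <- new.env(parent = emptyenv())
h2_matrix <- function(bands, fs, n) {
  key <- paste(n, fs, paste(bands$low_hz, bands$high_hz, collapse = ";"))
  got <- .h2_cache[[key]]
  if (!is.null(got)) return(got)
  H2 <- vapply(seq_len(nrow(bands)),
               function(b) butter_h2(c(bands$low_hz[b], bands$high_hz[b]), fs, n),
               numeric(n))
  .h2_cache[[key]] <- H2
  H2
}

#' Differential entropy of a sample window (Gaussian closed form)
#'
#' Computes `0.5 * log(2 * pi * e * var(x))` in nats, with the unbiased
#' sample variance floored at `var_floor` to avoid `-Inf` on degenerate
#' (near-constant) windows. A warning is raised when the floor engages.
#'
#' @param window numeric vector of length >= 2.
#' @param var_floor variance floor (default `1e-12`).
#' @return differential entropy in nats.
#' @export
#' @examples
#' differential_entropy(rnorm(1000))            # about 0.5 * log(2 * pi * e)
#' differential_entropy(2 * rnorm(1000))        # about log(2) higher
differential_entropy <- function(window, var_floor = 1e-12) {
  if (length(window) < 2L) stop("window must hold at least 2 samples",
                                call. = FALSE)
  v <- stats::var(window)
  if (v < var_floor) {
    warning("window variance ", signif(v, 3), " floored at ", var_floor)
    v <- var_floor
  }
  0.5 * log(2 * pi * exp(1) * v)
}

#' Extract differential-entropy band features from a raw trial
#'
#' For each channel and band, the signal is band-pass filtered (zero-phase
#' 4th-order Butterworth), split into non-overlapping windows of `window_s`
#' seconds, the Gaussian-form differential entropy is computed per window,
#' and windows are averaged ("averaged over time"). Features are assembled
#' channel-major: all bands of channel 1, then channel 2, and so on; 62
#' channels x 5 bands gives the conventional 310-vector.
#'
#' @param raw numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param bands a [band_spec()].
#' @param window_s window length in seconds (default 1).
#' @param method `"fft"` (batch frequency-domain path, the default) or
#'   `"filtfilt"` (time-domain path). Both apply the same squared-magnitude
#'   Butterworth response; they differ only in boundary handling.
#' @param var_floor per-window variance floor.
#' @return numeric feature vector of length `nrow(raw) * nrow(bands)`.
#' @export
extract_de_features <- function(raw, fs, bands = default_band_spec(),
                                window_s = 1, method = c("fft", "filtfilt"),
                                var_floor = 1e-12) {
  method <- match.arg(method)
  stopifnot(is.matrix(raw))
  n <- ncol(raw)
  win <- as.integer(round(window_s * fs))
  if (n < win) {
    stop("signal too short: ", n, " samples < one window of ", win,
         " samples (minimum length ", win, ")", call. = FALSE)
  }
  if (any(bands$high_hz >= fs / 2)) {
    stop("band edge at or above Nyquist frequency ", fs / 2, " Hz",
         call. = FALSE)
  }
  if (method == "fft") {
    de <- de_extract_cpp(raw, h2_matrix(bands, fs, n), win, var_floor)
  } else {
    nb <- nrow(bands)
    nw <- n %/% win
    de <- matrix(0, nrow(raw), nb)
    for (b in seq_len(nb)) {
      bf <- signal::butter(4, c(bands$low_hz[b], bands$high_hz[b]) / (fs / 2),
                           type = "pass")
      for (ch in seq_len(nrow(raw))) {
        y <- signal::filtfilt(bf, raw[ch, ])
        des <- vapply(seq_len(nw), function(w) {
          seg <- y[((w - 1) * win + 1):(w * win)]
          v <- stats::var(seg)
          0.5 * log(2 * pi * exp(1) * max(v, var_floor))
        }, numeric(1))
        de[ch, b] <- mean(des)
      }
    }
  }
  as.numeric(t(de))
}
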