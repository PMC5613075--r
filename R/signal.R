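#' Magnitude series of a tri-axial channel group
#'
#' Collapses the three axes of an accelerometer (or gyroscope) channel group
#' into a univariate magnitude series, the Euclidean norm of the 3-vector at
#' each time index. Raw sensor units are kept, gravity included: no filtering
#' or normalisation is applied, so the classifier sees the signal the sensor
#' recorded.
#'
#' @param recording A `recording` object (see [new_recording()]) or a data
#'   frame with columns `ax, ay, az` (and optionally `gx, gy, gz`).
#' @param channels `"accel"` or `"gyro"`.
#' @return A tibble with columns `t` (seconds, if available) and `magnitude`,
#'   carrying the sample rate and source in attributes `sample_rate` and
#'   `source`.
#' @examples
#' rec <- tibble::tibble(t = 0:3 / 100, ax = c(3, 0, 1, 0),
#'                       ay = c(4, 0, 0, 1), az = c(0, 0, 0, 0))
#' magnitude(rec)$magnitude
#' @export
magnitude <- function(recording, channels = c("accel", "gyro")) {
  channels <- match.arg(channels)
  df <- if (inherits(recording, "recording")) recording$data else recording
  cols <- if (channels == "accel") c("ax", "ay", "az") else c("gx", "gy", "gz")
  if (!all(cols %in% names(df))) {
    stop("channel absent: recording has no ", channels, " channels (",
         paste(setdiff(cols, names(df)), collapse = ", "), " missing)",
         call. = FALSE)
  }
  m <- as.matrix(df[cols])
  if (!all(is.finite(m))) stop("invalid sample: non-finite value in ", channels,
                               " channels", call. = FALSE)
  out <- tibble::tibble(
    t = if ("t" %in% names(df)) df$t else seq_len(nrow(df)) - 1,
    magnitude = sqrt(rowSums(m^2))
  )
  attr(out, "sample_rate") <- if (inherits(recording, "recording")) {
    recording$sample_rate
  } else {
    attr(recording, "sample_rate")
  }
  attr(out, "source") <- paste0(
    if (inherits(recording, "recording")) recording$recording_id else "series",
    ":", channels)
  out
}

#' Overlapping sliding windows of a series
#'
#' Cuts a univariate series of length L into the L - width + 1 overlapping
#' windows obtained by sliding a window of `width` samples one sample at a
#' time. With the default width of 32 at 100 Hz each window spans 0.32 s and a
#' series of length L yields exactly L - 31 windows.
#'
#' @param series Numeric vector, or a tibble with a `magnitude` column as
#'   returned by [magnitude()].
#' @param width Window length in samples (default 32).
#' @param stride Hop between consecutive windows in samples (default 1).
#' @return A numeric matrix with one window per row and `width` columns.
#' @export
extract_windows <- function(series, width = 32L, stride = 1L) {
  x <- series_values(series)
  width <- as.integer(width)
  stride <- as.integer(stride)
  stopifnot(width >= 1L, stride >= 1L)
  L <- length(x)
  if (L < width) {
    stop("series too short: length ", L, " < window width ", width,
         call. = FALSE)
  }
  starts <- seq.int(1L, L - width + 1L, by = stride)
  idx <- outer(starts, 0:(width - 1L), `+`)
  out <- matrix(x[idx], nrow = length(starts), ncol = width)
  dimnames(out) <- NULL
  out
}

series_values <- function(series) {
  if (is.data.frame(series)) {
    if (!"magnitude" %in% names(series)) {
      stop("expected a numeric vector or a tibble with a 'magnitude' column",
           call. = FALSE)
    }
    as.numeric(series$magnitude)
  } else {
    as.numeric(series)
  }
}

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# One-sided power spectrum of a single segment, normalised so that
# sum(power) equals the variance of the tapered segment (Parseval).
# Returns power at frequencies k * fs / n, k = 1 .. floor(n/2) (DC dropped).
one_sided_power <- function(x, taper = NULL) {
  n <- length(x)
  x <- x - mean(x)
  if (!is.null(taper)) x <- x * taper
  sc <- if (is.null(taper)) n else sum(taper^2)
  p2 <- Mod(stats::fft(x))^2 / (n * sc)
  half <- floor(n / 2)
  p <- 2 * p2[2:(half + 1)]
  if (n %% 2 == 0) p[half] <- p[half] / 2 # Nyquist bin is not mirrored
  p
}

#' Long-term spectral density features
#'
#' Welch-style averaged periodogram of a magnitude series (segments of 256
#' samples, 50% overlap, Hann taper), reduced to 32 densities by averaging
#' the periodogram within 32 equal-width frequency intervals tiling
#' (0, Nyquist] Hz. At the 100 Hz sample rate this is 32 bins of 1.5625 Hz
#' covering 0-50 Hz; the DC component is excluded. These 32 densities are the
#' terminal inputs of the long-term spectral classifier.
#'
#' @param series Numeric vector or magnitude tibble; at least 64 samples.
#' @param sample_rate Samples per second; must be 100 (the sensor rate).
#' @return A tibble with 32 rows and columns `bin` (1-32), `f_lo`, `f_hi`
#'   (Hz) and `density`.
#' @export
long_term_spectrum <- function(series, sample_rate = 100) {
  x <- series_values(series)
  if (length(x) < 64) {
    stop("insufficient samples: need >= 64, got ", length(x), call. = FALSE)
  }
  if (!isTRUE(all.equal(sample_rate, 100))) {
    stop("sample_rate must be 100 Hz (Nyquist 50 Hz); resampling is out of scope",
         call. = FALSE)
  }
  seg_len <- min(256L, length(x))
  hop <- max(1L, seg_len %/% 2L)
  starts <- seq.int(1L, length(x) - seg_len + 1L, by = hop)
  taper <- hann_window(seg_len)
  pows <- vapply(starts, function(s) {
    one_sided_power(x[s:(s + seg_len - 1L)], taper)
  }, numeric(floor(seg_len / 2)))
  pow <- rowMeans(pows)
  freqs <- seq_along(pow) * sample_rate / seg_len
  nyq <- sample_rate / 2
  edges <- seq(0, nyq, length.out = 33)
  bin <- pmin(32L, findInterval(freqs, edges, left.open = TRUE))
  density <- vapply(1:32, function(b) {
    if (any(bin == b)) mean(pow[bin == b]) else 0
  }, numeric(1))
  tibble::tibble(bin = 1:32, f_lo = edges[1:32], f_hi = edges[2:33],
                 density = density)
}

#' Short-term spectral density features of one window
#'
#' Spectral variant evaluated window by window: each 32-sample window is
#' zero-padded to 64 samples and a single (untapered) periodogram is taken;
#' the 32 one-sided bins above DC are the features. Padding is what makes a
#' 32-sample window, which natively has only 16 one-sided non-DC bins, yield
#' the 32 inputs the classifier geometry expects.
#'
#' @param window Numeric vector of exactly 32 samples.
#' @return Numeric vector of 32 non-negative densities.
#' @seealso [short_term_spectra()] for the vectorised form over a window
#'   matrix.
#' @export
short_term_spectrum <- function(window) {
  window <- as.numeric(window)
  if (length(window) != 32) {
    stop("bad window: expected 32 samples, got ", length(window), call. = FALSE)
  }
  short_term_spectra(matrix(window, nrow = 1))[1, ]
}

#' Short-term spectra of every window in a window matrix
#'
#' @param windows Matrix with 32 columns, one window per row (see
#'   [extract_windows()]).
#' @return Matrix of the same row count with 32 spectral density columns.
#' @export
short_term_spectra <- function(windows) {
  if (ncol(windows) != 32) {
    stop("bad window: expected 32 columns, got ", ncol(windows), call. = FALSE)
  }
  padded <- cbind(windows, matrix(0, nrow(windows), 32))
  ft <- stats::mvfft(t(padded))
  p2 <- Mod(ft)^2 / (64 * 32)
  p <- 2 * p2[2:33, , drop = FALSE]
  p[32, ] <- p[32, ] / 2 # bin 32 is the unmirrored Nyquist bin of the padded FFT
  t(p)
}
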