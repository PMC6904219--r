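#' Morlet wavelet time-frequency power
#'
#' Convolves each epoch with complex Morlet wavelets (Gaussian-windowed
#' complex exponentials with \code{sigma_t = n_cycles / (2 pi f)}, unit
#' energy) and returns squared magnitude as power. Time points whose wavelet
#' support (3 sigma_t) extends past the epoch edge are flagged invalid
#' rather than padded; analysis windows are expected to avoid them.
#'
#' @param epochs Either a trials x samples matrix (single electrode, as
#'   produced by \code{\link{simulate_eeg_epochs}}) or a 3-D array
#'   electrodes x samples x trials.
#' @param fs Sampling rate in Hz.
#' @param freqs Frequencies of interest in Hz (default 8-30 in 0.5 steps).
#' @param n_cycles Wavelet cycles (default 6).
#' @param times_s Optional output time points (seconds, relative to epoch
#'   start unless \code{t0} shifts them); defaults to every sample.
#' @param t0 Time of the first sample (default 0; use -1 for epochs cut
#'   from -1 s).
#' @return List of class \code{tfr_power}: \code{power} (electrodes x
#'   frequencies x times x trials), \code{freqs_hz}, \code{times_s},
#'   \code{fs}, \code{baseline_state} (\code{"raw"}), \code{valid}
#'   (frequencies x times logical).
#' @export
morlet_tfr <- function(epochs, fs, freqs = seq(8, 30, by = 0.5),
                       n_cycles = 6, times_s = NULL, t0 = 0) {
  stopifnot(n_cycles >= 1)
  if (any(freqs >= fs / 2)) {
    stop("requested frequency at or above Nyquist (", fs / 2, " Hz)",
         call. = FALSE)
  }
  if (is.matrix(epochs)) {
    x <- array(t(epochs), dim = c(1, ncol(epochs), nrow(epochs)))
  } else {
    x <- epochs
  }
  n_elec <- dim(x)[1]; n_samp <- dim(x)[2]; n_trials <- dim(x)[3]
  samp_t <- t0 + (seq_len(n_samp) - 1) / fs
  if (is.null(times_s)) times_s <- samp_t
  t_idx <- vapply(times_s, function(t) which.min(abs(samp_t - t)), integer(1))
  sigma_t <- n_cycles / (2 * pi * freqs)
  if (max(6 * sigma_t) > n_samp / fs) {
    stop("epoch too short for the lowest-frequency wavelet (needs ",
         signif(max(6 * sigma_t), 3), " s)", call. = FALSE)
  }
  # wavelets built in time domain, fft-convolved; wavelet centred at sample 1
  # with circular wrap so output is aligned with the input samples
  half <- ceiling(5 * max(sigma_t) * fs)
  wav_f <- matrix(0 + 0i, length(freqs), n_samp)
  tw <- c(0:half, -(half:1)) / fs
  for (fi in seq_along(freqs)) {
    w <- exp(-tw^2 / (2 * sigma_t[fi]^2)) * exp(2i * pi * freqs[fi] * tw)
    w <- w / sqrt(sum(Mod(w)^2) / fs)  # unit energy
    wfull <- complex(length.out = n_samp)
    wfull[c(1:(half + 1), (n_samp - half + 1):n_samp)] <-
      w[c(1:(half + 1), (half + 2):(2 * half + 1))]
    wav_f[fi, ] <- stats::fft(wfull)
  }
  power <- array(NA_real_, c(n_elec, length(freqs), length(t_idx), n_trials))
  for (e in seq_len(n_elec)) {
    for (tr in seq_len(n_trials)) {
      X <- stats::fft(x[e, , tr])
      for (fi in seq_along(freqs)) {
        y <- stats::fft(X * Conj(wav_f[fi, ]), inverse = TRUE) / (n_samp * fs)
        power[e, fi, , tr] <- Mod(y[t_idx])^2
      }
    }
  }
  valid <- outer(sigma_t, samp_t[t_idx], function(s, t) {
    t - t0 >= 3 * s & (samp_t[n_samp] - t) >= 3 * s
  })
  structure(list(power = power, freqs_hz = freqs, times_s = samp_t[t_idx],
                 fs = fs, baseline_state = "raw", valid = valid),
            class = "tfr_power")
}

#' z-transform time-frequency power across time and trials
#'
#' Per electrode and frequency, subtracts the mean and divides by the
#' standard deviation of power pooled over all time points and all trials
#' jointly, so each electrode-frequency stratum is on a common scale.
#'
#' @param tfr A raw \code{tfr_power}.
#' @return The \code{tfr_power} with z-scored power and
#'   \code{baseline_state = "ztransformed"}.
#' @export
baseline_ztransform <- function(tfr) {
  stopifnot(inherits(tfr, "tfr_power"))
  if (tfr$baseline_state != "raw") {
    stop("power is already z-transformed", call. = FALSE)
  }
  d <- dim(tfr$power)
  if (d[3] * d[4] < 2) stop("need >= 2 time x trial samples", call. = FALSE)
  for (e in seq_len(d[1])) {
    for (fi in seq_len(d[2])) {
      v <- tfr$power[e, fi, , ]
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) {
        stop("zero power SD at electrode ", e, ", frequency ",
             tfr$freqs_hz[fi], " Hz", call. = FALSE)
      }
      tfr$power[e, fi, , ] <- (v - mean(v)) / s
    }
  }
  tfr$baseline_state <- "ztransformed"
  tfr
}

#' Average power in a time window and frequency band per trial
#'
#' Collapses a (typically z-transformed) time-frequency representation to
#' one scalar per trial: the mean over the selected electrodes, the
#' frequency band and the time window. Used for post-stimulus
#' (500-1500 ms) and pre-stimulus (-1000 to -375 ms) alpha/beta (8-30 Hz)
#' power, and for narrower-band specificity variants.
#'
#' @param tfr A \code{tfr_power}.
#' @param window_s Length-2 time window (inclusive), seconds.
#' @param band_hz Length-2 frequency band (inclusive), Hz.
#' @param electrodes Electrode indices (default all).
#' @return Numeric vector, one value per trial.
#' @export
band_window_average <- function(tfr, window_s, band_hz, electrodes = NULL) {
  stopifnot(inherits(tfr, "tfr_power"))
  ei <- electrodes %||% seq_len(dim(tfr$power)[1])
  fi <- which(tfr$freqs_hz >= band_hz[1] & tfr$freqs_hz <= band_hz[2])
  ti <- which(tfr$times_s >= window_s[1] & tfr$times_s <= window_s[2])
  if (length(ei) == 0 || length(fi) == 0 || length(ti) == 0) {
    stop("empty electrode/band/window selection", call. = FALSE)
  }
  apply(tfr$power[ei, fi, ti, , drop = FALSE], 4, mean)
}

#' Welch power spectral density (Hann window, 50% overlap)
#'
#' @param x Numeric time series.
#' @param fs Sampling rate in Hz.
#' @param seg_s Segment length in seconds (default \code{min(length(x)/fs, 1)}).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return List with \code{freqs_hz} and \code{psd} (one-sided density).
#' @export
welch_psd <- function(x, fs, seg_s = NULL, overlap = 0.5) {
  n <- length(x)
  seg_s <- seg_s %||% min(n / fs, 1)
  L <- round(seg_s * fs)
  if (L < 8) stop("PSD segment too short: need at least 8 samples (",
                  signif(8 / fs, 3), " s)", call. = FALSE)
  if (L > n) stop("signal shorter than the PSD segment (needs >= ",
                  signif(L / fs, 3), " s)", call. = FALSE)
  step <- max(1, round(L * (1 - overlap)))
  starts <- seq(1, n - L + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))  # Hann
  scale <- fs * sum(w^2)
  nf <- floor(L / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2 / scale
    acc <- acc + P[seq_len(nf)]
  }
  psd <- acc / length(starts)
  psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]  # one-sided
  list(freqs_hz = (seq_len(nf) - 1) * fs / L, psd = psd)
}

#' IRASA fractal/oscillatory decomposition with 1/f slope fit
#'
#' Irregular-resampling auto-spectral analysis: the signal is resampled by
#' each non-integer factor h and its reciprocal; a power-law (fractal)
#' spectrum is unmoved by the geometric mean of each resampled pair's PSD,
#' whereas narrowband oscillatory peaks are displaced to f*h and f/h and
#' cancel. The median across the h set estimates the fractal spectrum; the
#' oscillatory spectrum is the residual original - fractal. The 1/f slope
#' and intercept come from a least-squares line fit to the fractal spectrum
#' in log10-log10 space, and oscillatory band power is the mean oscillatory
#' PSD over \code{osc_band_hz} (default 8-25 Hz; the highest trustworthy
#' frequency is about fs divided by four, i.e. Nyquist over the largest
#' resampling factor).
#'
#' @param epochs Numeric vector (one signal) or trials x samples matrix;
#'   spectra are computed per trial and averaged before decomposition
#'   output.
#' @param fs Sampling rate in Hz.
#' @param h_set Resampling factors (> 1); default \code{seq(1.1, 1.9, 0.05)}.
#' @param seg_s Welch segment length in seconds (default
#'   \code{min(epoch, 1)}).
#' @param fit_band_hz Band for the log-log slope fit (default 1-25 Hz).
#' @param osc_band_hz Band for oscillatory power (default 8-25 Hz).
#' @return List of class \code{irasa_result}: \code{freqs_hz},
#'   \code{original_psd}, \code{fractal_psd}, \code{oscillatory_psd},
#'   \code{slope}, \code{intercept}, \code{osc_band_power}, \code{h_set}.
#' @export
irasa_decompose <- function(epochs, fs, h_set = seq(1.1, 1.9, by = 0.05),
                            seg_s = NULL, fit_band_hz = c(1, 25),
                            osc_band_hz = c(8, 25)) {
  if (any(h_set <= 1)) stop("all h_set factors must exceed 1", call. = FALSE)
  f_max <- fs / (2 * max(h_set))
  if (fit_band_hz[2] > f_max || osc_band_hz[2] > f_max) {
    stop("band exceeds the maximum derivable frequency fs / (2 * h_max) = ",
         signif(f_max, 4), " Hz", call. = FALSE)
  }
  if (is.vector(epochs)) epochs <- matrix(epochs, nrow = 1)
  n <- ncol(epochs)
  # default segment must fit the shortest (most downsampled) resampling
  seg_s <- seg_s %||% min(1, (n / fs) / max(h_set))
  L <- round(seg_s * fs)
  # rational approximations of h on a 1/20 grid
  frac <- lapply(h_set, function(h) {
    q <- 20; p <- round(h * q); g <- gcd_int(p, q); c(p / g, q / g)
  })
  orig <- NULL
  fractal <- NULL
  for (tr in seq_len(nrow(epochs))) {
    x <- epochs[tr, ]
    ps <- welch_psd(x, fs, seg_s)
    hspec <- matrix(NA_real_, length(h_set), length(ps$psd))
    for (i in seq_along(h_set)) {
      p <- frac[[i]][1]; q <- frac[[i]][2]
      up <- signal::resample(x, p, q)
      dn <- signal::resample(x, q, p)
      # same segment length in samples => identical frequency grid
      psd_up <- welch_psd(up, fs, L / fs)$psd
      psd_dn <- welch_psd(dn, fs, L / fs)$psd
      hspec[i, ] <- sqrt(psd_up * psd_dn)
    }
    frac_tr <- apply(hspec, 2, stats::median)
    orig <- if (is.null(orig)) ps$psd else orig + ps$psd
    fractal <- if (is.null(fractal)) frac_tr else fractal + frac_tr
    freqs <- ps$freqs_hz
  }
  orig <- orig / nrow(epochs)
  fractal <- fractal / nrow(epochs)
  osc <- orig - fractal
  fit_i <- which(freqs >= fit_band_hz[1] & freqs <= fit_band_hz[2] &
                   fractal > 0 & freqs > 0)
  fit <- stats::lm.fit(cbind(1, log10(freqs[fit_i])),
                       log10(fractal[fit_i]))
  osc_i <- which(freqs >= osc_band_hz[1] & freqs <= osc_band_hz[2])
  structure(list(freqs_hz = freqs, original_psd = orig,
                 fractal_psd = fractal, oscillatory_psd = osc,
                 slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 osc_band_power = mean(osc[osc_i]), h_set = h_set),
            class = "irasa_result")
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Reliability of the 1/f slope estimate versus epoch length
#'
#' Simulates coloured-noise epochs of increasing length at a known aperiodic
#' exponent, estimates the 1/f slope of each with IRASA, and tabulates the
#' mean and SD of the estimates per length. Short epochs yield unstable
#' slopes; the SD shrinks as epochs lengthen.
#'
#' @param slope True aperiodic exponent chi (PSD ~ f^-chi); the fitted slope
#'   recovers -chi.
#' @param lengths_s Ascending epoch lengths in seconds.
#' @param n_reps Replicates per length (>= 2).
#' @param fs Sampling rate in Hz (default 200).
#' @param seed Integer seed; replicate seeds are derived deterministically.
#' @param ... Passed to \code{\link{irasa_decompose}}.
#' @return data.frame with \code{length_s}, \code{mean_slope},
#'   \code{sd_slope}, \code{n_reps}.
#' @export
epoch_length_reliability <- function(slope, lengths_s, n_reps, fs = 200,
                                     seed = 1, ...) {
  stopifnot(!is.unsorted(lengths_s), n_reps >= 2)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(1e7, length(lengths_s) * n_reps),
                      length(lengths_s))
  res <- lapply(seq_along(lengths_s), function(li) {
    est <- vapply(seq_len(n_reps), function(r) {
      ep <- simulate_eeg_epochs(1, fs, lengths_s[li], slope = slope,
                                osc_amp = 0, seed = rep_seeds[li, r])
      irasa_decompose(ep[1, ], fs, ...)$slope
    }, numeric(1))
    data.frame(length_s = lengths_s[li], mean_slope = mean(est),
               sd_slope = stats::sd(est), n_reps = n_reps)
  })
  do.call(rbind, res)
}
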