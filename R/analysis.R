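#' Binned spike counts
#'
#' Spike trains are analysed at a sampling rate of 256 Hz, i.e. counted in
#' bins of 1000/256 ms (~3.9 ms).
#'
#' @param times Spike-time vector (ms) or a list of per-neuron vectors.
#' @param t_start,t_end Analysis window (ms).
#' @param fs Sampling rate (Hz).
#' @return A numeric vector of counts, or a matrix (neurons x bins) when a
#'   list is given.
#' @export
bin_spikes <- function(times, t_start, t_end, fs = 256) {
  stopifnot(t_end > t_start, fs > 0)
  bw <- 1000 / fs
  nb <- floor((t_end - t_start) / bw)
  edges <- t_start + bw * (0:nb)
  one <- function(tt) {
    tt <- tt[tt >= t_start & tt < t_start + nb * bw]
    tabulate(findInterval(tt, edges), nbins = nb)
  }
  if (is.list(times)) t(vapply(times, one, numeric(nb))) else one(times)
}

#' Population Fano factor
#'
#' Synchrony measure: the variance of the binned population spike count
#' divided by its mean (population variance, i.e. the 1/n form). A value
#' of 1 corresponds to independent Poisson firing; larger values indicate
#' that spikes from different neurons cluster in time.
#'
#' @param counts Per-bin population counts, or a neurons-x-bins matrix
#'   (summed over neurons).
#' @export
fano_factor <- function(counts) {
  if (is.matrix(counts)) counts <- colSums(counts)
  if (length(counts) < 2) stop("need at least two bins")
  m <- mean(counts)
  if (m == 0) stop("zero mean count: Fano factor undefined")
  mean((counts - m)^2) / m
}

# Welch-averaged power spectra of one or several binned series.
# Disjoint Hanning-windowed segments, per-segment mean removal.
welch_psd <- function(x, fs = 256, nwin = 256) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  L <- floor(n / nwin)
  if (L < 1) stop("series shorter than one window")
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nwin - 1)) / nwin)
  wnorm <- sum(w^2)
  nf <- nwin %/% 2 + 1
  S <- numeric(nf)
  for (r in seq_len(nrow(x))) {
    for (l in seq_len(L)) {
      seg <- x[r, ((l - 1) * nwin + 1):(l * nwin)]
      seg <- (seg - mean(seg)) * w
      X <- fft(seg)[1:nf]
      S <- S + Mod(X)^2 / (wnorm * fs)
    }
  }
  list(freq = (0:(nf - 1)) * fs / nwin, S = S / (L * nrow(x)), L = L)
}

#' Oscillation index
#'
#' Relative spectral power in a frequency band (default 15-25 Hz, the beta
#' band): the power spectrum is estimated per neuron from its binned,
#' mean-subtracted spike train (Welch-averaged Hanning segments), averaged
#' over neurons, and integrated over the band relative to the full range
#' up to the Nyquist frequency.
#'
#' @param trains List of per-neuron spike-time vectors (ms).
#' @param t_start,t_end Analysis window (ms).
#' @param band Frequency band `c(a, b)` (Hz).
#' @param fs Sampling rate (Hz).
#' @param nwin Window length in samples (256 gives 1-Hz resolution at
#'   256 Hz; use 2048 for slow-wave work at 0.125 Hz).
#' @return Scalar in [0, 1].
#' @export
oscillation_index <- function(trains, t_start, t_end, band = c(15, 25),
                              fs = 256, nwin = 256) {
  if (!is.list(trains)) trains <- list(trains)
  if (sum(lengths(trains)) == 0) stop("empty spike trains")
  x <- bin_spikes(trains, t_start, t_end, fs)
  ps <- welch_psd(x, fs, nwin)
  inband <- ps$freq >= band[1] & ps$freq < band[2]
  total <- ps$freq > 0
  sum(ps$S[inband]) / sum(ps$S[total])
}

#' Spike-train coherence
#'
#' Magnitude-squared coherence between two binned spike trains from
#' disjoint Hanning-windowed segments, with the significance level
#' `1 - (1 - p)^(1/(L - 1))` for `L` independent segments.
#'
#' @param a,b Spike-time vectors (ms).
#' @param t_start,t_end Analysis window (ms).
#' @param nwin Segment length in samples.
#' @param fs Sampling rate (Hz).
#' @param p Confidence level for the significance threshold.
#' @return List with `freq`, `coh`, `signif`, `L`.
#' @export
spike_coherence <- function(a, b, t_start, t_end, nwin = 256, fs = 256,
                            p = 0.95) {
  xa <- bin_spikes(a, t_start, t_end, fs)
  xb <- bin_spikes(b, t_start, t_end, fs)
  n <- length(xa)
  L <- floor(n / nwin)
  if (L < 2) stop("need at least two segments")
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nwin - 1)) / nwin)
  nf <- nwin %/% 2 + 1
  Saa <- Sbb <- numeric(nf)
  Sab <- complex(real = numeric(nf))
  for (l in seq_len(L)) {
    ia <- ((l - 1) * nwin + 1):(l * nwin)
    A <- fft((xa[ia] - mean(xa[ia])) * w)[1:nf]
    B <- fft((xb[ia] - mean(xb[ia])) * w)[1:nf]
    Saa <- Saa + Mod(A)^2
    Sbb <- Sbb + Mod(B)^2
    Sab <- Sab + A * Conj(B)
  }
  coh <- Mod(Sab)^2 / (Saa * Sbb)
  coh[Saa == 0 | Sbb == 0] <- NA_real_
  list(freq = (0:(nf - 1)) * fs / nwin, coh = coh,
       signif = 1 - (1 - p)^(1 / (L - 1)), L = L)
}

# Analytic signal via FFT (Hilbert transform).
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Phase relation between two spike trains
#'
#' Both trains are binned at 256 Hz, band-pass filtered with a zero-phase
#' (forward-backward) Butterworth filter (0.5-1.5 Hz for slow-wave, 15-25
#' Hz for beta), converted to instantaneous phase via the analytic signal,
#' and the pointwise phase difference is histogrammed in 100 bins over
#' [-pi, pi). In-phase firing concentrates mass near 0, antiphase near
#' +/- pi.
#'
#' @param a,b Spike-time vectors (ms); `a` leading means positive phase.
#' @param t_start,t_end Analysis window (ms).
#' @param band `c(low, high)` Hz.
#' @param fs Sampling rate (Hz).
#' @param nbins Histogram bins.
#' @param order Butterworth order.
#' @return List with `breaks`, `mass` (sums to 1), `circ_mean` (rad) and
#'   `resultant` (mean vector length).
#' @export
phase_relation <- function(a, b, t_start, t_end, band = c(15, 25),
                           fs = 256, nbins = 100, order = 2) {
  if (length(a) == 0 || length(b) == 0) stop("empty spike trains")
  xa <- bin_spikes(a, t_start, t_end, fs)
  xb <- bin_spikes(b, t_start, t_end, fs)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  fa <- signal::filtfilt(bf, xa - mean(xa))
  fb <- signal::filtfilt(bf, xb - mean(xb))
  pa <- Arg(analytic_signal(fa))
  pb <- Arg(analytic_signal(fb))
  d <- (pa - pb + pi) %% (2 * pi) - pi
  breaks <- seq(-pi, pi, length.out = nbins + 1)
  mass <- tabulate(findInterval(d, breaks, rightmost.closed = TRUE),
                   nbins = nbins)
  z <- mean(exp(1i * d))
  list(breaks = breaks, mass = mass / sum(mass),
       circ_mean = Arg(z), resultant = Mod(z))
}

#' Classify a selection trial
#'
#' An action is selected when its output-nucleus (SNr) pool rate during
#' the 100-ms selection phase drops below half of the control-model
#' baseline for that pool.
#'
#' @param rates Numeric vector of per-action SNr pool rates (Hz) during
#'   the selection phase.
#' @param baseline Control baseline rate(s), recycled over actions.
#' @return One of `"none"`, `"action1"`, `"action2"`, ..., `"dual"`.
#' @export
classify_selection <- function(rates, baseline) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("baseline must be positive")
  sel <- rates < 0.5 * rep_len(baseline, length(rates))
  if (!any(sel)) "none"
  else if (sum(sel) > 1) "dual"
  else paste0("action", which(sel))
}

#' Selection-outcome grid summary
#'
#' Aggregates per-trial outcomes over a factor grid into per-cell outcome
#' proportions (the quantities drawn as pie charts).
#'
#' @param outcomes data.frame with columns `i`, `j`, `outcome`.
#' @return data.frame with one row per (i, j, outcome) and column `prop`;
#'   proportions sum to 1 within each cell.
#' @export
outcome_grid_summary <- function(outcomes) {
  stopifnot(nrow(outcomes) > 0)
  lv <- c("none", "action1", "action2", "dual")
  agg <- stats::aggregate(list(n = rep(1, nrow(outcomes))),
                          by = list(i = outcomes$i, j = outcomes$j,
                                    outcome = factor(outcomes$outcome,
                                                     levels = lv)),
                          FUN = sum, drop = FALSE)
  agg$n[is.na(agg$n)] <- 0
  tot <- stats::ave(agg$n, agg$i, agg$j, FUN = sum)
  agg$prop <- agg$n / tot
  agg
}

#' Interspike-interval CV
#'
#' Coefficient of variation of interspike intervals, averaged over the
#' neurons with at least `min_spikes` spikes.
#'
#' @param trains List of spike-time vectors (ms).
#' @param min_spikes Minimum spikes per neuron to enter the average.
#' @export
isi_cv <- function(trains, min_spikes = 3) {
  cvs <- vapply(trains, function(tt) {
    if (length(tt) < min_spikes) return(NA_real_)
    d <- diff(sort(tt))
    sd(d) / mean(d)
  }, numeric(1))
  mean(cvs, na.rm = TRUE)
}
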