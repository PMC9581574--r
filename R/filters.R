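# IIR filter design and zero-phase application.
#
# No filter-design package ships with the target environment, so the classic
# recipe is implemented here: analog Butterworth prototype -> frequency
# transform (lowpass / bandpass) with prewarped corners -> bilinear transform
# -> polynomial transfer function. Application uses stats::filter (C loops)
# for speed; zero-phase filtering runs the filter forward and backward over an
# odd-reflection-padded trace.

poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

butter_prototype_poles <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

bilinear_zpk <- function(z, p, k, fs) {
  fs2 <- 2 * fs
  kd <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  # poles in excess of zeros map to z = -1
  zd <- c(zd, rep(-1 + 0i, length(p) - length(z)))
  list(z = zd, p = pd, k = kd)
}

zpk_to_ba <- function(zpk) {
  b <- Re(poly_from_roots(zpk$z)) * zpk$k
  a <- Re(poly_from_roots(zpk$p))
  list(b = b, a = a)
}

#' Design a digital Butterworth filter
#'
#' `type = "low"` gives an order-`n` lowpass with corner `fc[1]`;
#' `type = "pass"` gives a bandpass of overall order `2n` with corners
#' `fc[1] < fc[2]` (so `n = 2` yields the 4th-order bandpass used by the
#' amplitude detector). Corners are prewarped before the bilinear transform.
#'
#' @param n Prototype order.
#' @param fc Corner frequency (Hz), length 1 for lowpass, 2 for bandpass.
#' @param fs Sampling rate (Hz).
#' @param type `"low"` or `"pass"`.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_design <- function(n, fc, fs, type = c("low", "pass")) {
  type <- match.arg(type)
  if (any(fc <= 0) || any(fc >= fs / 2)) {
    lfp_abort("corner frequencies must lie strictly inside (0, fs/2)", "lfpmon_parameter_error")
  }
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  proto <- butter_prototype_poles(n)
  if (type == "low") {
    wc <- warp(fc[1])
    zpk <- list(z = complex(0), p = proto * wc, k = wc^n)
  } else {
    if (length(fc) != 2 || fc[1] >= fc[2]) {
      lfp_abort("bandpass needs fc = c(low, high) with low < high", "lfpmon_parameter_error")
    }
    w1 <- warp(fc[1]); w2 <- warp(fc[2])
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    half <- proto * bw / 2
    disc <- sqrt(half^2 - w0^2)
    zpk <- list(z = rep(0 + 0i, n), p = c(half + disc, half - disc), k = bw^n)
  }
  zpk_to_ba(bilinear_zpk(zpk$z, zpk$p, zpk$k, fs))
}

#' Apply an IIR filter (single pass)
#'
#' Direct-form application with zero initial conditions:
#' `a[1] y[t] = sum(b * x[t..]) - sum(a[-1] * y[t-..])`.
#'
#' @param b,a Transfer-function coefficients.
#' @param x Numeric vector.
#' @return Filtered vector, same length as `x`.
#' @export
iir_filter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb - 1 + seq_along(x)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Zero-phase filtering (forward-backward)
#'
#' Filters forward then backward so the net phase response is zero and peak
#' timing is preserved. Edges are handled by odd reflection over a pad sized
#' to several time constants of the slowest filter pole.
#'
#' @param b,a Transfer-function coefficients.
#' @param x Numeric vector.
#' @param pad Pad length in samples; default scales with the filter's slowest
#'   dynamics and is capped at `length(x) - 1`.
#' @return Zero-phase filtered vector, same length as `x`.
#' @export
filtfilt <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (n < 3) return(iir_filter(b, a, rev(iir_filter(b, a, rev(x)))))
  if (is.null(pad)) {
    r <- Mod(polyroot(rev(a)))
    r <- r[r < 1]
    pad <- if (length(r)) ceiling(-7 / log(max(max(r), 0.5))) else 3 * length(a)
    pad <- max(pad, 3 * (max(length(a), length(b)) - 1))
  }
  pad <- min(pad, n - 1)
  front <- 2 * x[1] - x[(pad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- iir_filter(b, a, c(front, x, back))
  y <- rev(iir_filter(b, a, rev(y)))
  y[pad + seq_len(n)]
}

# --- blocked overlap-save correlation ---------------------------------------
# Shared engine for the sliding-window DFT and FIR filtering on long traces:
# the trace is cut into blocks of B samples overlapping by L-1, transformed
# once with mvfft, and each kernel costs one batched inverse transform.

os_block_fft <- function(x, L, n_out) {
  B <- max(4096L, stats::nextn(4L * L, 2))
  step <- B - L + 1L
  n_blocks <- max(1L, ceiling(n_out / step))
  idx <- outer(seq_len(B), (seq_len(n_blocks) - 1L) * step, `+`)
  xp <- c(x, rep(0, max(0L, max(idx) - length(x))))
  list(X = stats::mvfft(matrix(xp[idx], nrow = B)),
       B = B, L = L, step = step, n_out = n_out)
}

# correlation of x with kernel h (length L): out[w] = sum_j x[w+j-1] * h[j]
os_correlate <- function(blocks, h) {
  B <- blocks$B; L <- blocks$L
  g <- stats::fft(c(rev(h), rep(0 + 0i, B - L)))
  Y <- stats::mvfft(blocks$X * g, inverse = TRUE)[L:B, , drop = FALSE] / B
  as.vector(Y)[seq_len(blocks$n_out)]
}

#' Zero-phase FIR lowpass (windowed sinc)
#'
#' Hamming-windowed sinc lowpass applied centred, so the symmetric impulse
#' response gives exactly zero phase. Edges are zero-padded.
#'
#' @param x Numeric vector.
#' @param fc Cutoff (Hz).
#' @param fs Sampling rate (Hz).
#' @param ntaps Odd tap count; default scales with `fs/fc` for a transition
#'   band comfortably narrower than the cutoff.
#' @return Filtered vector, same length as `x`.
#' @export
fir_lowpass <- function(x, fc, fs, ntaps = NULL) {
  if (is.null(ntaps)) ntaps <- ceiling(16 * fs / fc)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1L
  m <- (ntaps - 1) / 2
  t <- seq(-m, m)
  h <- 2 * fc / fs * sinc(2 * fc / fs * t) * (0.54 + 0.46 * cos(pi * t / m))
  h <- h / sum(h)
  n <- length(x)
  xp <- c(rep(0, m), x, rep(0, m))
  blocks <- os_block_fft(xp, ntaps, n)
  Re(os_correlate(blocks, h))
}

sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

#' Downsample a trace to a target rate
#'
#' Anti-aliased by default: a zero-phase windowed-sinc lowpass at 0.45x the
#' target rate precedes keeping every k-th sample. The rate ratio must be an
#' integer. `antialias = FALSE` gives plain decimation for strict parity with
#' acquisition software whose decimator is undocumented.
#'
#' @param x Numeric vector sampled at `fs`.
#' @param fs Input sampling rate (Hz).
#' @param target_hz Output rate (Hz); must divide `fs`.
#' @param antialias Apply the protective lowpass first?
#' @return Vector of length `floor(length(x) * target_hz / fs)`.
#' @export
downsample_trace <- function(x, fs, target_hz, antialias = TRUE) {
  if (target_hz > fs) {
    lfp_abort("target rate exceeds the sampling rate", "lfpmon_parameter_error")
  }
  k <- fs / target_hz
  if (abs(k - round(k)) > 1e-9) {
    lfp_abort(sprintf("sample_rate/downsample ratio must be an integer (got %g)", k),
              "lfpmon_parameter_error")
  }
  k <- as.integer(round(k))
  if (k == 1L) return(x)
  if (antialias) x <- fir_lowpass(x, 0.45 * target_hz, fs)
  x[seq.int(1L, by = k, length.out = length(x) %/% k)]
}
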