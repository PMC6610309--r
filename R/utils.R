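# Low-level numerical helpers shared by the simulator and the detector.

#' Block-mean decimation
#'
#' Averages consecutive blocks of `k` samples. The tail that does not fill a
#' complete block is dropped. Acts as a crude low-pass + downsample, which is
#' all the DC-shift envelope needs.
#'
#' @param x numeric vector.
#' @param k integer block length, >= 1.
#' @return numeric vector of length `floor(length(x) / k)`.
#' @keywords internal
block_mean <- function(x, k) {
  k <- as.integer(k)
  if (k < 1L) stop("block length must be >= 1")
  if (k == 1L) return(x)
  n <- (length(x) %/% k) * k
  if (n == 0L) return(numeric(0))
  .colMeans(x[seq_len(n)], k, n %/% k)
}

#' Causal rolling median
#'
#' Median over the `width` samples strictly preceding each position (a lag of
#' one sample), so a value never contributes to its own baseline. Implemented
#' as a lagged centred running median: exact enough for a baseline estimate
#' and O(n log w) instead of O(n w).
#'
#' @param x numeric vector.
#' @param width window length in samples.
#' @return numeric vector, same length as `x`; the first `width` entries are
#'   backfilled with the first computed value.
#' @keywords internal
rolling_baseline <- function(x, width) {
  width <- as.integer(width)
  n <- length(x)
  if (n == 0L) stop("empty signal")
  if (width >= n) return(rep(stats::median(x), n))
  k <- width + (1L - width %% 2L)  # odd window for runmed
  rm <- stats::runmed(x, k, endrule = "median")
  lag <- (k %/% 2L) + 1L           # centre of window ends just before t
  b <- c(rep(rm[1L], lag), rm[seq_len(n - lag)])
  b
}

#' FFT band-pass filter
#'
#' Zero-phase band-pass by zeroing Fourier bins outside `band`. Intended for
#' short segments (an event plus its pre-event baseline), where edge effects
#' of the implicit circular convolution are handled by mirror padding.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param band numeric length-2, (low, high) in Hz; high is capped at Nyquist.
#' @return filtered numeric vector, same length as `x`.
#' @keywords internal
fft_bandpass <- function(x, fs, band) {
  n <- length(x)
  if (n < 8L) return(rep(0, n))
  if (band[1L] >= fs / 2) stop("band lower edge at or above Nyquist")
  hi <- min(band[2L], fs / 2)
  # mirror-pad to soften wrap-around; zero-pad to a 2-3-5-smooth length so
  # the mixed-radix FFT stays O(n log n)
  pad <- min(n, max(16L, as.integer(fs)))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[seq.int(n - pad + 1L, n)]))
  xp <- c(xp, numeric(stats::nextn(length(xp), c(2L, 3L, 5L)) - length(xp)))
  np <- length(xp)
  f <- (seq_len(np) - 1L) / np * fs
  f <- pmin(f, fs - f)  # two-sided frequency axis
  keep <- f >= band[1L] & f <= hi
  X <- stats::fft(xp)
  X[!keep] <- 0+0i
  y <- Re(stats::fft(X, inverse = TRUE)) / np
  y[seq.int(pad + 1L, pad + n)]
}

#' Running maximum over a symmetric window
#'
#' Iterative-doubling pmax; the effective half-window is the smallest
#' 2^k - 1 >= `half_width`, i.e. slightly larger than requested, which is
#' fine for an envelope estimate.
#'
#' @param x numeric vector.
#' @param half_width window half-width in samples.
#' @return numeric vector of local maxima.
#' @keywords internal
running_max <- function(x, half_width) {
  n <- length(x)
  r <- x
  s <- 1L
  while (s <= half_width && s < n) {
    r <- pmax(r,
              c(r[-seq_len(s)], rep(r[n], s)),
              c(rep(r[1L], s), r[seq_len(n - s)]))
    s <- s * 2L
  }
  r
}

#' Derive reproducible child seeds from a master seed
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in [1, 2^31 - 2].
#' @keywords internal
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Evaluate an expression with a local RNG seed
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# truncated-normal draws by resampling; bounds are physical limits, not tuning
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lower), upper))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  guard <- 0L
  while (length(bad) > 0L && guard < 100L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
    guard <- guard + 1L
  }
  pmin(pmax(x, lower), upper)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
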