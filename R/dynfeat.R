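dyn_time_names <- c("mean", "abs_mean", "rms", "sra", "std", "variance",
                    "maximum", "minimum", "peak_to_peak", "skewness",
                    "kurtosis", "waveform_factor", "crest_factor",
                    "impulse_factor")
dyn_freq_names <- c("dc", "mean_spectrum", "fc", "msf", "rmsf", "vf", "rvf",
                    "spectral_skewness", "spectral_kurtosis",
                    "spectral_entropy")

#' Dynamic feature names
#'
#' The 24 dynamic feature names (14 time-domain followed by 10
#' frequency-domain) applied to each static-feature trajectory.
#' @return character vector of length 24.
#' @export
dynamic_feature_names <- function() c(dyn_time_names, dyn_freq_names)

#' Time-domain features of a feature trajectory
#'
#' The 14 time-domain descriptors of a static feature's per-frame curve,
#' in order: mean, absolute mean, root-mean-square, square-root amplitude
#' ((sum sqrt|x|/N)^2), standard deviation, variance, maximum, minimum,
#' peak-to-peak, skewness, kurtosis, waveform factor (rms/absolute mean),
#' crest factor (max|x|/rms) and impulse factor (max|x|/absolute mean).
#' Population (N) denominators throughout; skewness and kurtosis of a
#' zero-variance series are 0, and any factor with a zero denominator is 0.
#'
#' @param x numeric series of length >= 8 (one value per frame).
#' @return named numeric vector of length 14.
#' @export
time_domain_features <- function(x) {
  n <- length(x)
  if (n < 8) stop("short series: need at least 8 frames", call. = FALSE)
  mu <- mean(x)
  am <- mean(abs(x))
  rms <- sqrt(mean(x^2))
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  mx <- max(x); mn <- min(x)
  pk <- max(abs(x))
  stats::setNames(c(
    mu, am, rms, mean(sqrt(abs(x)))^2, sqrt(m2), m2, mx, mn, mx - mn,
    if (m2 > 0) m3 / m2^1.5 else 0,
    if (m2 > 0) m4 / m2^2 else 0,
    if (am > 0) rms / am else 0,
    if (rms > 0) pk / rms else 0,
    if (am > 0) pk / am else 0), dyn_time_names)
}

#' Frequency-domain features of a feature trajectory
#'
#' Takes the FFT of the series and summarises its one-sided magnitude
#' spectrum \eqn{P_k = |X_k|} over bins \eqn{k = 1..\lfloor N/2 \rfloor} at
#' frequencies \eqn{f_k = k/N} cycles/frame. Emits, in order: dc
#' (\eqn{|X_0|/N}), mean spectrum, center-of-gravity frequency fc, mean
#' square frequency msf, root mean square frequency rmsf, variance
#' frequency vf, root variance frequency rvf, spectral skewness and
#' kurtosis (standardised moments of the spectrum about fc) and normalised
#' spectral entropy (log2, divided by log2 of the bin count). A spectrum
#' with total mass 0 (constant series) yields zero for all moments.
#'
#' @param x numeric series of length >= 8.
#' @return named numeric vector of length 10; `fc` and `rmsf` lie in
#'   `[0, 0.5]` cycles/frame and `msf >= fc^2`.
#' @export
frequency_domain_features <- function(x) {
  n <- length(x)
  if (n < 8) stop("short series: need at least 8 frames", call. = FALSE)
  X <- stats::fft(x)
  k <- seq_len(n %/% 2)
  P <- Mod(X[k + 1L])
  f <- k / n
  dc <- Mod(X[1]) / n
  tot <- sum(P)
  if (tot > 0) {
    p <- P / tot
    fc <- sum(f * p)
    msf <- sum(f^2 * p)
    vf <- sum((f - fc)^2 * p)
    ssk <- if (vf > 0) sum((f - fc)^3 * p) / vf^1.5 else 0
    sku <- if (vf > 0) sum((f - fc)^4 * p) / vf^2 else 0
    pp <- p[p > 0]
    sent <- if (length(P) > 1) -sum(pp * log2(pp)) / log2(length(P)) else 0
  } else {
    fc <- msf <- vf <- ssk <- sku <- sent <- 0
  }
  stats::setNames(c(dc, mean(P), fc, msf, sqrt(msf), vf, sqrt(vf), ssk, sku,
                    sent), dyn_freq_names)
}

#' Dynamic feature vector of one video
#'
#' Converts a static feature matrix (frames x 91) into the video's dynamic
#' feature vector: for each static feature's trajectory, the 14 time-domain
#' and 10 frequency-domain descriptors, named
#' `<static_feature>.<dynamic_feature>`, 91 x 24 = 2184 values in total.
#'
#' @param sfm a static feature matrix tibble from
#'   [extract_static_features()] (>= 8 frames).
#' @param registry the [feature_registry()] naming the static columns.
#' @return one-row tibble with `case_id` and 2184 feature columns.
#' @export
extract_dynamic_vector <- function(sfm, registry = feature_registry()) {
  stopifnot(all(registry$names %in% names(sfm)))
  vals <- purrr::map(registry$names, function(nm) {
    x <- sfm[[nm]]
    v <- c(time_domain_features(x), frequency_domain_features(x))
    stats::setNames(v, paste(nm, names(v), sep = "."))
  })
  v <- unlist(vals)
  dplyr::bind_cols(
    tibble::tibble(case_id = sfm$case_id[1]),
    tibble::as_tibble(as.list(v)))
}
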