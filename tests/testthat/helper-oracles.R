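# Independent brute-force oracles. These deliberately re-derive every
# quantity from its definition (explicit loops, direct summation) and share
# no code with the package implementation.

oracle_quantile <- function(x, p) {
  # type-7 linear interpolation, written out from the definition
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  xs[lo] + (h - floor(h)) * (xs[hi] - xs[lo])
}

oracle_first_order <- function(x, bins = 32) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  lo <- min(x); hi <- max(x)
  if (hi > lo) {
    cnt <- numeric(bins)
    for (v in x) {
      b <- floor((v - lo) / (hi - lo) * bins)
      if (b >= bins) b <- bins - 1
      cnt[b + 1] <- cnt[b + 1] + 1
    }
    p <- cnt / n
  } else p <- c(1, numeric(bins - 1))
  ent <- 0
  for (pi in p) if (pi > 0) ent <- ent - pi * log2(pi)
  q10 <- oracle_quantile(x, 0.10); q90 <- oracle_quantile(x, 0.90)
  band <- x[x >= q10 & x <= q90]
  c(fo_mean = mu,
    fo_median = oracle_quantile(x, 0.5),
    fo_min = lo, fo_max = hi, fo_range = hi - lo,
    fo_variance = m2, fo_sd = sqrt(m2),
    fo_skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    fo_kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    fo_energy = sum(x^2), fo_rms = sqrt(sum(x^2) / n),
    fo_entropy = ent, fo_uniformity = sum(p^2),
    fo_p10 = q10, fo_p90 = q90,
    fo_iqr = oracle_quantile(x, 0.75) - oracle_quantile(x, 0.25),
    fo_mad = sum(abs(x - mu)) / n,
    fo_rmad = if (length(band)) sum(abs(band - mean(band))) / length(band)
              else 0,
    fo_cv = if (m2 > 0 && mu != 0) sqrt(m2) / mu else 0)
}

# symmetric normalized co-occurrence features by explicit pixel-pair loops
oracle_glcm <- function(q, levels, offsets) {
  out <- numeric(0)
  for (ang in names(offsets)) {
    dr <- offsets[[ang]][1]; dc <- offsets[[ang]][2]
    C <- matrix(0, levels, levels)
    for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
      r2 <- r + dr; c2 <- cc + dc
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q) &&
          !is.na(q[r, cc]) && !is.na(q[r2, c2])) {
        i <- q[r, cc] + 1; j <- q[r2, c2] + 1
        C[i, j] <- C[i, j] + 1
        C[j, i] <- C[j, i] + 1
      }
    }
    feats <- setNames(numeric(11),
                      c("contrast", "dissimilarity", "homogeneity", "asm",
                        "energy", "correlation", "entropy", "cluster_shade",
                        "cluster_prominence", "max_prob", "sum_average"))
    if (sum(C) > 0) {
      P <- C / sum(C)
      mu_i <- 0; mu_j <- 0
      for (i in 1:levels) for (j in 1:levels) {
        mu_i <- mu_i + (i - 1) * P[i, j]
        mu_j <- mu_j + (j - 1) * P[i, j]
      }
      var_i <- 0; var_j <- 0; cov_ij <- 0
      for (i in 1:levels) for (j in 1:levels) {
        var_i <- var_i + (i - 1 - mu_i)^2 * P[i, j]
        var_j <- var_j + (j - 1 - mu_j)^2 * P[i, j]
        cov_ij <- cov_ij + (i - 1 - mu_i) * (j - 1 - mu_j) * P[i, j]
      }
      for (i in 1:levels) for (j in 1:levels) {
        p <- P[i, j]; d <- (i - 1) - (j - 1); s <- (i - 1) + (j - 1)
        feats["contrast"] <- feats["contrast"] + d^2 * p
        feats["dissimilarity"] <- feats["dissimilarity"] + abs(d) * p
        feats["homogeneity"] <- feats["homogeneity"] + p / (1 + d^2)
        feats["asm"] <- feats["asm"] + p^2
        if (p > 0) feats["entropy"] <- feats["entropy"] - p * log2(p)
        feats["cluster_shade"] <- feats["cluster_shade"] +
          (s - mu_i - mu_j)^3 * p
        feats["cluster_prominence"] <- feats["cluster_prominence"] +
          (s - mu_i - mu_j)^4 * p
        feats["sum_average"] <- feats["sum_average"] + s * p
      }
      feats["energy"] <- sqrt(feats["asm"])
      feats["max_prob"] <- max(P)
      feats["correlation"] <- if (var_i > 0 && var_j > 0)
        cov_ij / sqrt(var_i * var_j) else 0
    }
    names(feats) <- paste0("glcm_", names(feats), "_", ang)
    out <- c(out, feats)
  }
  out
}

# per-pixel neighborhood-loop LBP (uniform rotation-invariant)
oracle_lbp_hist <- function(frame, mask, P, R) {
  rpad <- ceiling(R)
  nr <- nrow(frame); nc <- ncol(frame)
  codes <- integer(0)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (r - rpad < 1 || r + rpad > nr || cc - rpad < 1 || cc + rpad > nc)
      next
    ok <- TRUE
    for (dr in -rpad:rpad) for (dc in -rpad:rpad)
      if (!mask[r + dr, cc + dc]) ok <- FALSE
    if (!ok) next
    s <- logical(P)
    for (p in 0:(P - 1)) {
      ang <- 2 * pi * p / P
      ry <- r - R * sin(ang); rx <- cc + R * cos(ang)
      y0 <- floor(ry); x0 <- floor(rx)
      fy <- ry - y0; fx <- rx - x0
      y1 <- min(y0 + 1, nr); x1 <- min(x0 + 1, nc)
      nv <- (1 - fy) * (1 - fx) * frame[y0, x0] +
        (1 - fy) * fx * frame[y0, x1] +
        fy * (1 - fx) * frame[y1, x0] + fy * fx * frame[y1, x1]
      s[p + 1] <- nv >= frame[r, cc] - 1e-8 * max(1, abs(frame[r, cc]))
    }
    u <- 0
    for (p in seq_len(P)) u <- u + abs(s[p] - s[if (p == P) 1 else p + 1])
    codes <- c(codes, if (u <= 2) sum(s) else P + 1)
  }
  h <- numeric(P + 2)
  if (length(codes)) {
    for (cd in codes) h[cd + 1] <- h[cd + 1] + 1
    h <- h / length(codes)
  }
  h
}

oracle_time_domain <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  am <- sum(abs(x)) / n
  rms <- sqrt(sum(x^2) / n)
  m2 <- sum((x - mu)^2) / n
  c(mean = mu, abs_mean = am, rms = rms,
    sra = (sum(sqrt(abs(x))) / n)^2,
    std = sqrt(m2), variance = m2, maximum = max(x), minimum = min(x),
    peak_to_peak = max(x) - min(x),
    skewness = if (m2 > 0) (sum((x - mu)^3) / n) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) (sum((x - mu)^4) / n) / m2^2 else 0,
    waveform_factor = if (am > 0) rms / am else 0,
    crest_factor = if (rms > 0) max(abs(x)) / rms else 0,
    impulse_factor = if (am > 0) max(abs(x)) / am else 0)
}

# direct DFT by explicit summation (no FFT)
oracle_dft_mod <- function(x, k) {
  n <- length(x)
  re <- 0; im <- 0
  for (t in 0:(n - 1)) {
    re <- re + x[t + 1] * cos(2 * pi * k * t / n)
    im <- im - x[t + 1] * sin(2 * pi * k * t / n)
  }
  sqrt(re^2 + im^2)
}

oracle_freq_domain <- function(x) {
  n <- length(x)
  K <- n %/% 2
  P <- vapply(1:K, function(k) oracle_dft_mod(x, k), numeric(1))
  f <- (1:K) / n
  dc <- oracle_dft_mod(x, 0) / n
  tot <- sum(P)
  if (tot > 0) {
    p <- P / tot
    fc <- sum(f * p); msf <- sum(f^2 * p); vf <- sum((f - fc)^2 * p)
    ssk <- if (vf > 0) sum((f - fc)^3 * p) / vf^1.5 else 0
    sku <- if (vf > 0) sum((f - fc)^4 * p) / vf^2 else 0
    pp <- p[p > 0]
    sent <- if (K > 1) -sum(pp * log2(pp)) / log2(K) else 0
  } else fc <- msf <- vf <- ssk <- sku <- sent <- 0
  c(dc = dc, mean_spectrum = mean(P), fc = fc, msf = msf, rmsf = sqrt(msf),
    vf = vf, rvf = sqrt(vf), spectral_skewness = ssk,
    spectral_kurtosis = sku, spectral_entropy = sent)
}

# all-pairs concordance AUC
oracle_auc <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}
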