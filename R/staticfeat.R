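#' Static radiomics feature registry
#'
#' Defines the ordered set of 91 static features extracted from each frame
#' and its ROI mask: 19 first-order intensity statistics, 28 local binary
#' pattern (LBP) histogram bins (uniform rotation-invariant, P=8/R=1 giving
#' 10 bins and P=16/R=2 giving 18), and 44 gray-level co-occurrence matrix
#' (GLCM) features (11 Haralick-style statistics at each of the four
#' distance-1 offsets 0, 45, 90, 135 degrees). Feature order is stable
#' across runs: first-order, then LBP, then GLCM.
#'
#' @param levels gray-level quantization levels for the GLCM (>= 2).
#' @return object of class `feature_registry` with `$names` (length 91),
#'   `$groups`, `$levels`, `$offsets` and `$lbp` settings.
#' @export
feature_registry <- function(levels = 32) {
  stopifnot(levels >= 2)
  fo <- paste0("fo_", c("mean", "median", "min", "max", "range", "variance",
                        "sd", "skewness", "kurtosis", "energy", "rms",
                        "entropy", "uniformity", "p10", "p90", "iqr", "mad",
                        "rmad", "cv"))
  lbp <- c(sprintf("lbp_p8r1_b%02d", 0:9), sprintf("lbp_p16r2_b%02d", 0:17))
  glcm_stats <- c("contrast", "dissimilarity", "homogeneity", "asm",
                  "energy", "correlation", "entropy", "cluster_shade",
                  "cluster_prominence", "max_prob", "sum_average")
  angles <- c(0, 45, 90, 135)
  glcm <- as.vector(vapply(angles, function(a)
    sprintf("glcm_%s_a%03d", glcm_stats, a), character(11)))
  nm <- c(fo, lbp, glcm)
  stopifnot(length(nm) == 91, !anyDuplicated(nm))
  structure(list(
    names = nm,
    groups = list(first_order = fo, binary_texture = lbp, glcm = glcm),
    levels = as.integer(levels),
    glcm_stats = glcm_stats,
    # (drow, dcol) at distance 1; rows grow downward
    offsets = list(a000 = c(0L, 1L), a045 = c(-1L, 1L),
                   a090 = c(-1L, 0L), a135 = c(-1L, -1L)),
    lbp = list(list(P = 8L, R = 1), list(P = 16L, R = 2))
  ), class = "feature_registry")
}

#' Serialise a feature registry to JSON
#' @param registry a [feature_registry()].
#' @param path output JSON path.
#' @export
write_registry_json <- function(registry, path) {
  jsonlite::write_json(unclass(registry), path, auto_unbox = TRUE)
  invisible(path)
}

#' Quantize ROI pixels to integer gray levels
#'
#' Uniformly bins ROI pixel values of `[lo, hi]` into `levels` integer
#' levels `0..levels-1`. The range is supplied externally so one range can
#' be shared by all frames of a video (a per-frame range would inject
#' artificial temporal variation into the feature trajectories). When
#' `hi == lo` all pixels map to level 0.
#'
#' @param frame numeric matrix.
#' @param mask logical matrix; must contain at least one `TRUE`.
#' @param levels number of gray levels (>= 2).
#' @param global_range numeric `(lo, hi)` shared across the video's frames.
#' @return integer matrix with quantized levels inside the mask and `NA`
#'   outside.
#' @export
quantize_roi <- function(frame, mask, levels, global_range) {
  if (!any(mask)) stop("degenerate ROI: empty mask", call. = FALSE)
  stopifnot(levels >= 2, length(global_range) == 2)
  lo <- global_range[1]; hi <- global_range[2]
  q <- matrix(NA_integer_, nrow(frame), ncol(frame))
  x <- frame[mask]
  if (hi == lo) {
    q[mask] <- 0L
  } else {
    lev <- floor((x - lo) / (hi - lo) * levels)
    q[mask] <- as.integer(pmin(pmax(lev, 0), levels - 1))
  }
  q
}

#' First-order intensity statistics of an ROI
#'
#' The 19 first-order features, in registry order: mean, median, minimum,
#' maximum, range, variance, standard deviation, skewness, kurtosis, energy
#' (sum of squares), root-mean-square, histogram entropy (32 bins, log2),
#' uniformity (sum of squared bin probabilities), 10th and 90th percentiles,
#' interquartile range, mean absolute deviation, robust mean absolute
#' deviation (restricted to the 10th-90th percentile band) and coefficient
#' of variation. Moments use population (n) denominators; skewness,
#' kurtosis and CV of a constant region are 0 by convention, and kurtosis
#' is the raw (non-excess) fourth standardised moment.
#'
#' @param x numeric vector of ROI pixel values (>= 1 value).
#' @param bins histogram bins for entropy/uniformity.
#' @return named numeric vector of length 19.
#' @export
first_order_features <- function(x, bins = 32) {
  if (length(x) == 0) stop("degenerate ROI: no pixels", call. = FALSE)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  sdev <- sqrt(m2)
  lo <- min(x); hi <- max(x)
  if (hi > lo) {
    b <- pmin(floor((x - lo) / (hi - lo) * bins), bins - 1)
    p <- tabulate(b + 1L, nbins = bins) / n
  } else {
    p <- c(1, numeric(bins - 1))
  }
  p_pos <- p[p > 0]
  qs <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  band <- x[x >= qs[1] & x <= qs[4]]
  rmad <- if (length(band) > 0) mean(abs(band - mean(band))) else 0
  c(fo_mean = mu,
    fo_median = stats::median(x),
    fo_min = lo,
    fo_max = hi,
    fo_range = hi - lo,
    fo_variance = m2,
    fo_sd = sdev,
    fo_skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    fo_kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    fo_energy = sum(x^2),
    fo_rms = sqrt(mean(x^2)),
    fo_entropy = -sum(p_pos * log2(p_pos)),
    fo_uniformity = sum(p^2),
    fo_p10 = qs[1],
    fo_p90 = qs[4],
    fo_iqr = qs[3] - qs[2],
    fo_mad = mean(abs(x - mu)),
    fo_rmad = rmad,
    fo_cv = if (sdev > 0 && mu != 0) sdev / mu else 0)
}

glcm_matrix <- function(q, offset, levels) {
  nr <- nrow(q); nc <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  ra <- max(1, 1 - dr); rb <- min(nr, nr - dr)
  ca <- max(1, 1 - dc); cb <- min(nc, nc - dc)
  if (ra > rb || ca > cb) return(NULL)
  r1 <- ra:rb
  c1 <- ca:cb
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) return(NULL)
  i <- a[keep]; j <- b[keep]
  counts <- tabulate(i * levels + j + 1L, nbins = levels^2) +
    tabulate(j * levels + i + 1L, nbins = levels^2)
  P <- matrix(counts / sum(counts), levels, levels)
  P
}

glcm_stats_from_P <- function(P) {
  levels <- nrow(P)
  idx <- 0:(levels - 1)
  I <- matrix(idx, levels, levels)
  J <- matrix(idx, levels, levels, byrow = TRUE)
  mu_i <- sum(I * P); mu_j <- sum(J * P)
  var_i <- sum((I - mu_i)^2 * P); var_j <- sum((J - mu_j)^2 * P)
  pp <- P[P > 0]
  corr <- if (var_i > 0 && var_j > 0)
    sum((I - mu_i) * (J - mu_j) * P) / sqrt(var_i * var_j) else 0
  c(contrast = sum((I - J)^2 * P),
    dissimilarity = sum(abs(I - J) * P),
    homogeneity = sum(P / (1 + (I - J)^2)),
    asm = sum(P^2),
    energy = sqrt(sum(P^2)),
    correlation = corr,
    entropy = -sum(pp * log2(pp)),
    cluster_shade = sum((I + J - mu_i - mu_j)^3 * P),
    cluster_prominence = sum((I + J - mu_i - mu_j)^4 * P),
    max_prob = max(P),
    sum_average = sum((I + J) * P))
}

#' Gray-level co-occurrence features of a quantized ROI
#'
#' For each of the four distance-1 offsets, accumulates the symmetric
#' normalized co-occurrence matrix over pixel pairs that both lie inside
#' the mask, and emits 11 statistics: contrast, dissimilarity, homogeneity,
#' angular second moment (ASM), energy (sqrt of ASM), correlation, entropy
#' (log2), cluster shade, cluster prominence, maximum probability and sum
#' average. Offsets with no valid pixel pair emit zeros; correlation of a
#' zero-variance matrix is 0 by convention.
#'
#' @param q quantized ROI (integer matrix with `NA` outside the mask, as
#'   produced by [quantize_roi()]).
#' @param registry a [feature_registry()] supplying levels and offsets.
#' @return named numeric vector of length 44 in registry order.
#' @export
glcm_features <- function(q, registry = feature_registry()) {
  out <- numeric(0)
  for (ang in names(registry$offsets)) {
    P <- glcm_matrix(q, registry$offsets[[ang]], registry$levels)
    v <- if (is.null(P)) stats::setNames(numeric(11), registry$glcm_stats)
         else glcm_stats_from_P(P)
    names(v) <- sprintf("glcm_%s_%s", registry$glcm_stats, ang)
    out <- c(out, v)
  }
  out
}

# Valid LBP centers: pixels whose full square neighborhood of radius rpad
# lies inside both the mask and the frame.
lbp_valid_centers <- function(mask, rpad) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (nr <= 2 * rpad || nc <= 2 * rpad) return(NULL)
  core <- matrix(FALSE, nr, nc)
  inner_r <- (1 + rpad):(nr - rpad)
  inner_c <- (1 + rpad):(nc - rpad)
  acc <- matrix(TRUE, length(inner_r), length(inner_c))
  for (dr in -rpad:rpad) for (dc in -rpad:rpad)
    acc <- acc & mask[inner_r + dr, inner_c + dc, drop = FALSE]
  core[inner_r, inner_c] <- acc
  if (!any(core)) return(NULL)
  which(core, arr.ind = TRUE)
}

lbp_codes <- function(frame, centers, P, R) {
  ncen <- nrow(centers)
  cv <- frame[centers]
  s <- matrix(FALSE, ncen, P)
  for (p in 0:(P - 1)) {
    ang <- 2 * pi * p / P
    dy <- -R * sin(ang)
    dx <- R * cos(ang)
    ry <- centers[, 1] + dy
    rx <- centers[, 2] + dx
    y0 <- floor(ry); x0 <- floor(rx)
    fy <- ry - y0; fx <- rx - x0
    # at integer sample positions the second index carries zero weight;
    # clamp it so it stays inside the frame
    y1 <- pmin(y0 + 1, nrow(frame)); x1 <- pmin(x0 + 1, ncol(frame))
    v00 <- frame[cbind(y0, x0)]
    v01 <- frame[cbind(y0, x1)]
    v10 <- frame[cbind(y1, x0)]
    v11 <- frame[cbind(y1, x1)]
    nv <- (1 - fy) * (1 - fx) * v00 + (1 - fy) * fx * v01 +
      fy * (1 - fx) * v10 + fy * fx * v11
    s[, p + 1] <- nv >= cv - 1e-8 * pmax(1, abs(cv))
  }
  trans <- rowSums(abs(s - s[, c(2:P, 1), drop = FALSE]))
  ones <- rowSums(s)
  ifelse(trans <= 2, ones, P + 1)
}

#' Local binary pattern histogram features of an ROI
#'
#' Computes uniform rotation-invariant LBP codes with bilinearly
#' interpolated circular neighbours under the tie convention
#' neighbour >= center -> 1, for two configurations (P=8, R=1) and
#' (P=16, R=2). Codes are computed only at pixels whose full neighbourhood
#' lies inside the mask; each configuration's histogram (P+2 bins) is
#' normalised to sum 1, or left all-zero when no pixel qualifies. The
#' concatenated output has 10 + 18 = 28 values.
#'
#' @param frame numeric frame matrix.
#' @param mask logical ROI mask.
#' @param registry a [feature_registry()] supplying the LBP settings.
#' @return named numeric vector of length 28.
#' @export
lbp_features <- function(frame, mask, registry = feature_registry()) {
  out <- numeric(0)
  for (cfg in registry$lbp) {
    P <- cfg$P; R <- cfg$R
    rpad <- ceiling(R)
    centers <- lbp_valid_centers(mask, rpad)
    h <- numeric(P + 2)
    if (!is.null(centers)) {
      codes <- lbp_codes(frame, centers, P, R)
      h <- tabulate(codes + 1L, nbins = P + 2) / length(codes)
    }
    names(h) <- sprintf("lbp_p%dr%d_b%02d", P, round(R), 0:(P + 1))
    out <- c(out, h)
  }
  out
}

#' Extract the static feature matrix of a video
#'
#' Computes, for every frame, the 91 static radiomics features over the
#' frame's ROI mask: first-order statistics of the raw ROI intensities, LBP
#' histograms, and GLCM features of the ROI quantized to the registry's
#' gray levels over a single global intensity range shared by all the
#' video's ROI pixels.
#'
#' @param frames list of numeric frame matrices.
#' @param roi_masks list of logical ROI masks, one per frame.
#' @param registry a [feature_registry()].
#' @param case_id identifier carried into the output.
#' @return tibble with columns `case_id`, `frame_index` (0-based) and the
#'   91 registry features; one row per frame, no missing values.
#' @export
extract_static_features <- function(frames, roi_masks,
                                    registry = feature_registry(),
                                    case_id = "case") {
  stopifnot(length(frames) == length(roi_masks))
  rng <- range(unlist(purrr::map2(frames, roi_masks, function(f, m) {
    if (!any(m)) stop("degenerate ROI: empty mask", call. = FALSE)
    range(f[m])
  })))
  rows <- matrix(NA_real_, length(frames), 91,
                 dimnames = list(NULL, registry$names))
  for (i in seq_along(frames)) {
    f <- frames[[i]]; m <- roi_masks[[i]]
    # crop to the mask bounding box: every feature depends only on ROI pixels
    idx <- which(m, arr.ind = TRUE)
    rr <- range(idx[, 1]); cc <- range(idx[, 2])
    fs <- f[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    ms <- m[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    vals <- fs[ms]
    fo <- tryCatch(first_order_features(vals), error = function(e)
      stop(sprintf("frame %d: %s", i - 1L, conditionMessage(e)),
           call. = FALSE))
    lbp <- lbp_features(fs, ms, registry)
    q <- quantize_roi(fs, ms, registry$levels, rng)
    gl <- glcm_features(q, registry)
    rows[i, ] <- c(fo, lbp, gl)[registry$names]
  }
  dplyr::bind_cols(
    tibble::tibble(case_id = case_id,
                   frame_index = seq_along(frames) - 1L),
    tibble::as_tibble(rows))
}
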