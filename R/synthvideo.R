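#' Configuration for a synthetic lesion-video cohort
#'
#' Builds a validated configuration object for [generate_cohort()]. The
#' generator emulates grayscale speckle ultrasound video containing a single
#' elliptical lesion whose echotexture (mean contrast against background) and
#' temporal modulation frequency differ between the HER2-negative and
#' HER2-positive classes, together with class-shifted clinical covariates.
#'
#' The lesion interior mean intensity follows
#' \deqn{m(t) = m_0 (1 + a \sin(2\pi f_{class} t + \phi))}
#' with \eqn{t} in frames, \eqn{a} = `mod_amplitude`, \eqn{f_{class}` the
#' class temporal frequency in cycles/frame, and a per-case random phase
#' \eqn{\phi}. Speckle is multiplicative gamma noise with unit mean whose
#' shape is chosen so the pixel standard deviation equals `noise_sigma`
#' gray levels; `noise_sigma = 0` gives the exact noiseless closed form.
#'
#' @param n_cases number of cases (>= 2).
#' @param positive_fraction fraction of HER2-positive cases, strictly in (0,1).
#' @param frame_count frames per video (>= 8).
#' @param frame_shape integer (rows, cols) of each frame.
#' @param lesion_axes_range range (min, max) in pixels for the lesion
#'   semi-major axis; the semi-minor axis is drawn as 0.5-0.9 of it.
#' @param texture_contrast named list with `negative_class` and
#'   `positive_class`: fractional lesion contrast against the background
#'   base level (negative = hypoechoic, i.e. darker lesion).
#' @param temporal_freq named list with `negative_class` and `positive_class`
#'   temporal modulation frequencies in cycles/frame, each in (0, 0.5).
#' @param mod_amplitude amplitude `a` of the sinusoidal lesion-mean
#'   modulation, as a fraction of the lesion base level.
#' @param noise_sigma speckle standard deviation in gray levels (0 disables
#'   noise entirely).
#' @param base_level background mean gray level (8-bit scale).
#' @param seed integer seed; identical configurations give bit-identical
#'   cohorts.
#' @return an object of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_cases = 4, frame_count = 8, frame_shape = c(48, 48))
#' cohort <- generate_cohort(cfg)
#' length(cohort)
synth_config <- function(n_cases,
                         positive_fraction = 0.5,
                         frame_count = 64,
                         frame_shape = c(128, 128),
                         lesion_axes_range = c(10, 22),
                         texture_contrast = list(negative_class = -0.30,
                                                 positive_class = -0.50),
                         temporal_freq = list(negative_class = 0.05,
                                              positive_class = 0.20),
                         mod_amplitude = 0.15,
                         noise_sigma = 12,
                         base_level = 170,
                         seed = 1L) {
  fail <- function(field, why) {
    stop(sprintf("invalid synth_config field `%s`: %s", field, why),
         call. = FALSE)
  }
  if (!is.numeric(n_cases) || length(n_cases) != 1 || n_cases < 2)
    fail("n_cases", "must be a single number >= 2")
  if (!is.numeric(positive_fraction) || length(positive_fraction) != 1 ||
      positive_fraction <= 0 || positive_fraction >= 1)
    fail("positive_fraction", "must be strictly between 0 and 1")
  if (!is.numeric(frame_count) || length(frame_count) != 1 || frame_count < 8)
    fail("frame_count", "must be >= 8")
  if (!is.numeric(frame_shape) || length(frame_shape) != 2 ||
      any(frame_shape < 16))
    fail("frame_shape", "must be two pixel counts >= 16")
  if (!is.numeric(lesion_axes_range) || length(lesion_axes_range) != 2 ||
      lesion_axes_range[1] <= 0 || diff(lesion_axes_range) < 0)
    fail("lesion_axes_range", "must be an increasing positive pair")
  for (fld in c("texture_contrast", "temporal_freq")) {
    v <- get(fld)
    if (!is.list(v) || !all(c("negative_class", "positive_class") %in% names(v)))
      fail(fld, "must name `negative_class` and `positive_class`")
  }
  tf <- unlist(temporal_freq[c("negative_class", "positive_class")])
  if (any(tf <= 0) || any(tf >= 0.5))
    fail("temporal_freq", "frequencies must lie in (0, 0.5) cycles/frame")
  if (!is.numeric(mod_amplitude) || mod_amplitude < 0 || mod_amplitude >= 1)
    fail("mod_amplitude", "must lie in [0, 1)")
  if (!is.numeric(noise_sigma) || noise_sigma < 0)
    fail("noise_sigma", "must be >= 0")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    fail("seed", "must be a single integer")
  structure(list(
    n_cases = as.integer(n_cases),
    positive_fraction = positive_fraction,
    frame_count = as.integer(frame_count),
    frame_shape = as.integer(frame_shape),
    lesion_axes_range = lesion_axes_range,
    texture_contrast = texture_contrast,
    temporal_freq = temporal_freq,
    mod_amplitude = mod_amplitude,
    noise_sigma = noise_sigma,
    base_level = base_level,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# Draw per-case geometry, dynamics, clinical covariates and a private RNG
# seed for frame rendering, so a case renders identically whether the cohort
# is materialised at once or streamed case by case.
synth_case_params <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_cases
  n_pos <- round(n * config$positive_fraction)
  out <- local({
    set.seed(config$seed)
    labels <- integer(n)
    labels[sample.int(n, n_pos)] <- 1L
    rows <- config$frame_shape[1]
    cols <- config$frame_shape[2]
    ax_rng <- config$lesion_axes_range
    a_ax <- stats::runif(n, ax_rng[1], ax_rng[2])
    b_ax <- a_ax * stats::runif(n, 0.5, 0.9)
    # keep the lesion comfortably inside the frame
    cy <- rows / 2 + stats::runif(n, -0.1, 0.1) * rows
    cx <- cols / 2 + stats::runif(n, -0.1, 0.1) * cols
    phase <- stats::runif(n, 0, 2 * pi)
    clin <- synth_clinical(labels)
    tibble::tibble(
      case_id = sprintf("case_%03d", seq_len(n)),
      label = labels,
      a_ax = a_ax, b_ax = b_ax, cy = cy, cx = cx, phase = phase,
      contrast = ifelse(labels == 1L,
                        config$texture_contrast$positive_class,
                        config$texture_contrast$negative_class),
      freq = ifelse(labels == 1L,
                    config$temporal_freq$positive_class,
                    config$temporal_freq$negative_class),
      render_seed = sample.int(.Machine$integer.max, n)
    ) |>
      dplyr::bind_cols(clin)
  })
  out
}

# Class-shifted clinical covariates with marginals matched in range to the
# study population: age ~ N(52, 10.6) clamped to [26, 83]; size ~ N(2.37,
# 1.1) truncated at 0.3 cm with a +0.4 cm shift for positives; meno ~
# Bernoulli(0.58); cN with P(cN>=1) raised by 0.15 for positives; cT and
# cTNM from the population frequencies.
synth_clinical <- function(labels) {
  n <- length(labels)
  pos <- labels == 1L
  age <- pmin(pmax(round(stats::rnorm(n, 52, 10.6)), 26), 83)
  size_cm <- pmax(stats::rnorm(n, 2.37 + 0.4 * pos, 1.1), 0.3)
  meno <- stats::rbinom(n, 1, 0.58)
  draw_ord <- function(p_neg, p_pos, codes) {
    vapply(seq_len(n), function(i) {
      p <- if (pos[i]) p_pos else p_neg
      sample(codes, 1, prob = p)
    }, numeric(1))
  }
  cN <- draw_ord(c(0.77, 0.22, 0.01), c(0.62, 0.37, 0.01), 0:2)
  cT <- draw_ord(c(0.48, 0.50, 0.02), c(0.48, 0.50, 0.02), 1:3)
  cTNM <- draw_ord(c(0.42, 0.56, 0.02), c(0.42, 0.56, 0.02), 1:3)
  tibble::tibble(age = as.numeric(age), size_cm = size_cm,
                 meno = as.integer(meno), cN = as.integer(cN),
                 cT = as.integer(cT), cTNM = as.integer(cTNM))
}

#' Render one frame of a synthetic lesion video
#'
#' Renders frame `t` for a single case: a speckled background around the
#' configured base level with an elliptical lesion whose interior mean
#' follows the case's sinusoidal modulation. Exposed mainly for inspection
#' and testing; [generate_cohort()] renders whole cases.
#'
#' @param t 0-based frame index in `[0, frame_count)`.
#' @param params one row of the internal per-case parameter table (a list or
#'   one-row data frame with `a_ax`, `b_ax`, `cy`, `cx`, `phase`, `contrast`,
#'   `freq`).
#' @param config the [synth_config()] used for the cohort.
#' @param speckle optional pre-drawn multiplicative speckle field (matrix of
#'   the frame shape); if `NULL`, drawn from the current RNG state.
#' @return list with `frame` (numeric matrix, 8-bit range) and `mask`
#'   (logical matrix, the rendered ellipse support).
#' @export
render_frame <- function(t, params, config, speckle = NULL) {
  if (!is.numeric(t) || length(t) != 1 || t < 0 || t >= config$frame_count)
    stop(sprintf("frame index %s out of range [0, %d)", t, config$frame_count),
         call. = FALSE)
  p <- as.list(params)
  rows <- config$frame_shape[1]
  cols <- config$frame_shape[2]
  yy <- matrix(seq_len(rows), rows, cols)
  xx <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  mask <- ((yy - p$cy) / p$b_ax)^2 + ((xx - p$cx) / p$a_ax)^2 <= 1
  m0 <- config$base_level * (1 + p$contrast)
  mt <- m0 * (1 + config$mod_amplitude * sin(2 * pi * p$freq * t + p$phase))
  level <- matrix(config$base_level, rows, cols)
  level[mask] <- mt
  if (config$noise_sigma > 0) {
    if (is.null(speckle)) {
      shape <- (level / config$noise_sigma)^2
      speckle <- stats::rgamma(rows * cols, shape = shape) / shape
    }
    frame <- level * speckle
  } else {
    frame <- level
  }
  frame <- pmin(pmax(frame, 0), 255)
  dim(frame) <- c(rows, cols)
  list(frame = frame, mask = mask)
}

render_case <- function(params, config) {
  p <- as.list(params)
  set.seed(p$render_seed)
  frames <- vector("list", config$frame_count)
  masks <- vector("list", config$frame_count)
  for (t in seq_len(config$frame_count) - 1L) {
    fr <- render_frame(t, p, config)
    frames[[t + 1L]] <- fr$frame
    masks[[t + 1L]] <- fr$mask
  }
  structure(list(
    case_id = p$case_id,
    frames = frames,
    truth_masks = masks,
    clinical = tibble::tibble(age = p$age, size_cm = p$size_cm,
                              meno = p$meno, cN = p$cN, cT = p$cT,
                              cTNM = p$cTNM),
    label = p$label
  ), class = "video_case")
}

#' Generate a synthetic lesion-video cohort
#'
#' Materialises `n_cases` synthetic video cases from a [synth_config()].
#' Exactly `round(n_cases * positive_fraction)` cases carry label 1
#' (HER2-positive). Identical configurations (including seed) produce
#' bit-identical cohorts.
#'
#' @param config a [synth_config()].
#' @return list of `video_case` objects, each with `case_id`, `frames`
#'   (list of numeric matrices), `truth_masks` (list of logical matrices),
#'   `clinical` (one-row tibble) and `label` (0/1).
#' @seealso [cohort_clinical()], [write_cohort()]
#' @export
generate_cohort <- function(config) {
  params <- synth_case_params(config)
  purrr::map(seq_len(nrow(params)),
             function(i) render_case(params[i, ], config))
}

#' Clinical covariate table of a cohort
#'
#' @param cohort list of `video_case` objects from [generate_cohort()].
#' @return tibble with columns case_id, age, size_cm, meno, cN, cT, cTNM,
#'   label (one row per case).
#' @export
cohort_clinical <- function(cohort) {
  purrr::map_dfr(cohort, function(cs) {
    dplyr::bind_cols(tibble::tibble(case_id = cs$case_id), cs$clinical,
                     tibble::tibble(label = cs$label))
  })
}

#' Write a cohort to disk as PNG frames plus clinical CSV
#'
#' Writes one directory per case containing `frame_0000.png...` and
#' `mask_0000.png...`, a cohort-level `clinical.csv` and the generating
#' configuration as `synth_config.json`. Frames are rounded to 8-bit on
#' write.
#'
#' @param cohort list of `video_case` objects.
#' @param dir output directory (created if needed).
#' @param config optional [synth_config()] to serialise alongside.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cs in cohort) {
    cdir <- file.path(dir, cs$case_id)
    dir.create(cdir, showWarnings = FALSE)
    for (i in seq_along(cs$frames)) {
      png::writePNG(round(cs$frames[[i]]) / 255,
                    file.path(cdir, sprintf("frame_%04d.png", i - 1L)))
      png::writePNG(cs$truth_masks[[i]] * 1,
                    file.path(cdir, sprintf("mask_%04d.png", i - 1L)))
    }
  }
  utils::write.csv(cohort_clinical(cohort),
                   file.path(dir, "clinical.csv"), row.names = FALSE)
  if (!is.null(config))
    jsonlite::write_json(unclass(config), file.path(dir, "synth_config.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing per-case subdirectories and clinical.csv.
#' @return list of `video_case` objects (frames restored to the 8-bit scale).
#' @export
read_cohort <- function(dir) {
  clin <- utils::read.csv(file.path(dir, "clinical.csv"))
  purrr::map(seq_len(nrow(clin)), function(i) {
    cdir <- file.path(dir, clin$case_id[i])
    ff <- sort(list.files(cdir, pattern = "^frame_\\d+\\.png$",
                          full.names = TRUE))
    mf <- sort(list.files(cdir, pattern = "^mask_\\d+\\.png$",
                          full.names = TRUE))
    structure(list(
      case_id = clin$case_id[i],
      frames = purrr::map(ff, function(f) png::readPNG(f) * 255),
      truth_masks = purrr::map(mf, function(f) png::readPNG(f) > 0.5),
      clinical = tibble::as_tibble(
        clin[i, c("age", "size_cm", "meno", "cN", "cT", "cTNM")]),
      label = clin$label[i]
    ), class = "video_case")
  })
}

#' Per-frame lesion mean-intensity trajectory
#'
#' Mean intensity over the truth mask (or any supplied per-frame masks) for
#' each frame; the curve whose spectral peak encodes the class's temporal
#' modulation frequency.
#'
#' @param case a `video_case`.
#' @param masks optional list of per-frame logical masks (defaults to the
#'   case's truth masks).
#' @return numeric vector of length `frame_count`.
#' @export
lesion_mean_curve <- function(case, masks = case$truth_masks) {
  vapply(seq_along(case$frames),
         function(i) mean(case$frames[[i]][masks[[i]]]), numeric(1))
}
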