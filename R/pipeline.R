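#' Extract the dynamic feature vector of one video case
#'
#' Runs the full per-case feature pipeline: lesion localisation (naive
#' intensity detector, or bypass with supplied/truth masks), track cleanup
#' (outlier rejection then linear interpolation), rectangular ROI
#' rasterisation, static feature extraction on every frame, and reduction
#' of each static feature's trajectory to its 24 dynamic descriptors.
#'
#' @param case a `video_case` (see [generate_cohort()]), or a list with
#'   `case_id` and `frames`.
#' @param registry a [feature_registry()].
#' @param use_truth_masks bypass the detector with the case's truth masks.
#' @param window,iou_min track-cleanup parameters (see [reject_outliers()]).
#' @param detector_args list of extra arguments for [detect_boxes_naive()].
#' @return list with `track` (cleaned [box_track]), `static` (frames x 91
#'   tibble) and `dynamic` (one-row tibble, 2184 features).
#' @export
extract_case_features <- function(case, registry = feature_registry(),
                                  use_truth_masks = FALSE,
                                  window = 5, iou_min = 0.3,
                                  detector_args = list()) {
  masks <- if (use_truth_masks) case$truth_masks else NULL
  track <- do.call(detect_boxes_naive,
                   c(list(frames = case$frames, masks = masks,
                          case_id = case$case_id), detector_args))
  track <- clean_track(track, window = window, iou_min = iou_min)
  shape <- dim(case$frames[[1]])
  roi <- track_to_roi_masks(track, shape)
  sfm <- extract_static_features(case$frames, roi, registry,
                                 case_id = case$case_id)
  list(track = track, static = sfm,
       dynamic = extract_dynamic_vector(sfm, registry))
}

#' Extract dynamic features for a whole cohort
#'
#' Maps [extract_case_features()] over a cohort and binds the per-case
#' dynamic vectors into one tibble (cases x 2184 features).
#'
#' @param cohort list of `video_case` objects.
#' @inheritParams extract_case_features
#' @return tibble with `case_id` and the 2184 dynamic feature columns.
#' @export
extract_cohort_features <- function(cohort, registry = feature_registry(),
                                    use_truth_masks = FALSE,
                                    window = 5, iou_min = 0.3,
                                    detector_args = list()) {
  purrr::map_dfr(cohort, function(cs)
    extract_case_features(cs, registry, use_truth_masks, window, iou_min,
                          detector_args)$dynamic)
}

#' Run the synthetic end-to-end study
#'
#' Generates a synthetic cohort (streamed case by case to bound memory),
#' extracts the dynamic features through the full detection/tracking
#' pipeline, splits 4:1, and either fits one fusion model or runs the
#' 4 x 4 base-model grid.
#'
#' @param config a [synth_config()].
#' @param split_seed seed for the train/test split. The default offsets
#'   the config seed so the split draws from an RNG stream unrelated to
#'   the one that assigned the class labels.
#' @param model_seed seed for the classifiers.
#' @param grid run the full [run_model_grid()] instead of a single fusion
#'   fit.
#' @param imaging_kind,clinical_kind base models when `grid = FALSE`.
#' @inheritParams extract_case_features
#' @inheritParams fit_fusion_model
#' @return list with `features`, `clinical`, `split` and either `grid`
#'   (a `model_grid`) or `model` + `predictions_train` /
#'   `predictions_test`.
#' @export
run_dlr_study <- function(config, split_seed = config$seed + 1L,
                          model_seed = config$seed, grid = FALSE,
                          imaging_kind = "xgb", clinical_kind = "lr",
                          w = 0.5, tau = 0.5, pca_threshold = 0.95,
                          use_truth_masks = FALSE,
                          registry = feature_registry()) {
  params <- synth_case_params(config)
  feats <- purrr::map_dfr(seq_len(nrow(params)), function(i) {
    cs <- render_case(params[i, ], config)
    extract_case_features(cs, registry,
                          use_truth_masks = use_truth_masks)$dynamic
  })
  clinical <- dplyr::bind_cols(
    params[, c("case_id", "age", "size_cm", "meno", "cN", "cT", "cTNM")],
    tibble::tibble(label = params$label))
  sp <- split_cohort(clinical, ratio = 0.8, seed = split_seed)
  f_tr <- feats[feats$case_id %in% sp$train, ]
  f_te <- feats[feats$case_id %in% sp$test, ]
  c_tr <- clinical[clinical$case_id %in% sp$train, ]
  c_te <- clinical[clinical$case_id %in% sp$test, ]
  out <- list(features = feats, clinical = clinical, split = sp)
  if (grid) {
    out$grid <- run_model_grid(f_tr, c_tr, f_te, c_te, w = w, tau = tau,
                               pca_threshold = pca_threshold,
                               seed = model_seed)
  } else {
    fm <- fit_fusion_model(f_tr, c_tr, imaging_kind, clinical_kind,
                           w = w, tau = tau, pca_threshold = pca_threshold,
                           seed = model_seed)
    out$model <- fm
    out$predictions_train <- stats::predict(fm, f_tr, c_tr)
    out$predictions_test <- stats::predict(fm, f_te, c_te)
  }
  out
}
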