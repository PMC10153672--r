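#' ROC area under the curve (Mann-Whitney form)
#'
#' AUC as the Mann-Whitney concordance probability: the fraction of
#' positive-negative pairs in which the positive scores higher, ties
#' counting one half.
#'
#' @param probabilities numeric scores.
#' @param labels binary 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(probabilities, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("undefined AUC: only one class present", call. = FALSE)
  r <- rank(probabilities)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts at a probability threshold
#'
#' Cases are called positive iff `p >= tau` (ties at the threshold count
#' as positive).
#'
#' @param probabilities numeric scores.
#' @param labels binary 0/1 labels.
#' @param tau decision threshold.
#' @return tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_threshold <- function(probabilities, labels, tau = 0.5) {
  call_pos <- probabilities >= tau
  tibble::tibble(
    tp = sum(call_pos & labels == 1),
    fp = sum(call_pos & labels == 0),
    tn = sum(!call_pos & labels == 0),
    fn = sum(!call_pos & labels == 1))
}

#' Performance metrics from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/n` and Youden index `sen + spc - 1`, alongside a supplied AUC.
#'
#' @param counts tibble or list with `tp`, `fp`, `tn`, `fn`.
#' @param auc AUC to carry into the row (optional).
#' @return one-row tibble with `auc`, `acc`, `sen`, `spc`, `yi`.
#' @export
metrics_from_confusion <- function(counts, auc = NA_real_) {
  c2 <- as.list(counts)
  n <- c2$tp + c2$fp + c2$tn + c2$fn
  if (n == 0) stop("undefined metric `acc`: no cases", call. = FALSE)
  if (c2$tp + c2$fn == 0)
    stop("undefined metric `sen`: no positives", call. = FALSE)
  if (c2$tn + c2$fp == 0)
    stop("undefined metric `spc`: no negatives", call. = FALSE)
  sen <- c2$tp / (c2$tp + c2$fn)
  spc <- c2$tn / (c2$tn + c2$fp)
  tibble::tibble(auc = auc, acc = (c2$tp + c2$tn) / n, sen = sen, spc = spc,
                 yi = sen + spc - 1)
}

#' Evaluate a prediction set
#'
#' Convenience wrapper: AUC plus thresholded confusion metrics.
#'
#' @inheritParams confusion_at_threshold
#' @return one-row tibble with `auc`, `acc`, `sen`, `spc`, `yi`.
#' @export
evaluate_predictions <- function(probabilities, labels, tau = 0.5) {
  metrics_from_confusion(confusion_at_threshold(probabilities, labels, tau),
                         auc = roc_auc(probabilities, labels))
}

resample_indices <- function(n, labels, m = n, max_tries = 10) {
  for (i in seq_len(max_tries)) {
    idx <- sample.int(n, m, replace = TRUE)
    if (length(unique(labels[idx])) == 2) return(idx)
  }
  NULL
}

#' Percentile bootstrap confidence interval for a prediction metric
#'
#' Resamples cases with replacement `B` times and returns the percentile
#' interval of the metric. Resamples lacking one of the classes are
#' redrawn (at most 10 times, then skipped with a warning).
#'
#' @param metric_fn function of `(probabilities, labels)` returning a
#'   scalar, e.g. [roc_auc()].
#' @param probabilities,labels the prediction set.
#' @param B number of bootstrap resamples (>= 100).
#' @param level confidence level.
#' @param seed integer seed.
#' @return named numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(metric_fn, probabilities, labels, B = 1000,
                         level = 0.95, seed = 1L) {
  if (B < 100) stop("B must be at least 100", call. = FALSE)
  set.seed(seed)
  n <- length(labels)
  vals <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- resample_indices(n, labels)
    if (is.null(idx)) {
      warning("bootstrap resample lacking a class skipped after 10 redraws")
      next
    }
    vals[b] <- metric_fn(probabilities[idx], labels[idx])
  }
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0)
    stop("metric undefined on every bootstrap resample", call. = FALSE)
  a <- (1 - level) / 2
  stats::setNames(stats::quantile(vals, c(a, 1 - a), names = FALSE),
                  c("lo", "hi"))
}

#' Paired repeated-resampling comparison of models
#'
#' Draws `R` resamples of `m` cases with replacement from a shared test
#' set; within each repetition every model is evaluated on the same
#' indices, giving paired per-repetition distributions of AUC, accuracy
#' and Youden index. Models are then compared with two-sided paired
#' t-tests on each metric.
#'
#' @param predictions named list of probability vectors, all aligned to
#'   the same cases.
#' @param labels shared binary labels.
#' @param R repetitions.
#' @param m resample size (default: the test-set size).
#' @param tau decision threshold for accuracy and Youden index.
#' @param seed integer seed.
#' @return object of class `comparison_report`: list with `draws` (tibble
#'   model x repetition x metric values), `tests` (pairwise paired t-test
#'   p-values per metric) and `winner` (model with the highest mean, per
#'   metric).
#' @export
repeated_resample_compare <- function(predictions, labels, R = 1000,
                                      m = length(labels), tau = 0.5,
                                      seed = 1L) {
  stopifnot(length(predictions) >= 2, !is.null(names(predictions)))
  n <- length(labels)
  set.seed(seed)
  models <- names(predictions)
  draws <- vector("list", R)
  for (r in seq_len(R)) {
    idx <- resample_indices(n, labels, m)
    if (is.null(idx)) {
      warning("resample lacking a class skipped after 10 redraws")
      next
    }
    draws[[r]] <- purrr::map_dfr(models, function(md) {
      mm <- evaluate_predictions(predictions[[md]][idx], labels[idx], tau)
      tibble::tibble(model = md, rep = r, auc = mm$auc, acc = mm$acc,
                     yi = mm$yi)
    })
  }
  draws <- dplyr::bind_rows(draws)
  pairs <- utils::combn(models, 2, simplify = FALSE)
  tests <- purrr::map_dfr(pairs, function(pr) {
    a <- draws[draws$model == pr[1], ]
    b <- draws[draws$model == pr[2], ]
    common <- intersect(a$rep, b$rep)
    a <- a[match(common, a$rep), ]; b <- b[match(common, b$rep), ]
    purrr::map_dfr(c("auc", "acc", "yi"), function(met) {
      d <- a[[met]] - b[[met]]
      p <- if (stats::sd(d) == 0) 1 else stats::t.test(d)$p.value
      tibble::tibble(model_a = pr[1], model_b = pr[2], metric = met,
                     mean_diff = mean(d), p_value = p)
    })
  })
  winner <- draws |>
    tidyr::pivot_longer(c("auc", "acc", "yi"), names_to = "metric") |>
    dplyr::group_by(.data$metric, .data$model) |>
    dplyr::summarise(mean = mean(.data$value), .groups = "drop_last") |>
    dplyr::slice_max(.data$mean, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  structure(list(draws = draws, tests = tests, winner = winner,
                 R = R, m = m),
            class = "comparison_report")
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return tibble of `(fpr, tpr, threshold)` points from the highest
#'   threshold down.
#' @export
roc_points <- function(probabilities, labels) {
  ord <- order(probabilities, decreasing = TRUE)
  p <- probabilities[ord]; y <- labels[ord]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  keep <- c(diff(p) != 0, TRUE)
  tibble::tibble(
    threshold = c(Inf, p[keep]),
    tpr = c(0, cumsum(y == 1)[keep] / n1),
    fpr = c(0, cumsum(y == 0)[keep] / n0))
}

#' Write a model-grid report as CSV
#'
#' One row per model and cohort (`T` training, `I-T` independent test)
#' with AUC/ACC/SEN/SPC/YI columns, mirroring the usual published layout.
#'
#' @param grid a `model_grid` from [run_model_grid()].
#' @param path CSV path.
#' @export
write_grid_csv <- function(grid, path) {
  long <- dplyr::bind_rows(
    dplyr::transmute(grid, .data$branch, .data$model, cohort = "T",
                     auc = .data$auc_train, acc = .data$acc_train,
                     sen = .data$sen_train, spc = .data$spc_train,
                     yi = .data$yi_train),
    dplyr::transmute(grid, .data$branch, .data$model, cohort = "I-T",
                     auc = .data$auc_test, acc = .data$acc_test,
                     sen = .data$sen_test, spc = .data$spc_test,
                     yi = .data$yi_test))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Boxplot comparison of resampled model metrics
#' @param object a `comparison_report`.
#' @param metric which metric distribution to show.
#' @param ... unused.
#' @method autoplot comparison_report
#' @export
autoplot.comparison_report <- function(object, metric = c("auc", "acc", "yi"),
                                       ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$model, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = toupper(metric),
                  title = sprintf("%d-repetition resampling comparison",
                                  object$R)) +
    ggplot2::theme_minimal()
}

#' Heatmap of fused test AUC over the 4 x 4 model grid
#' @param object a `model_grid`.
#' @param ... unused.
#' @method autoplot model_grid
#' @export
autoplot.model_grid <- function(object, ...) {
  fused <- object[object$branch == "fused", ]
  ggplot2::ggplot(fused,
                  ggplot2::aes(x = kind_label(.data$clinical_kind),
                               y = kind_label(.data$imaging_kind),
                               fill = .data$auc_test)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$auc_test)), size = 3) +
    ggplot2::scale_fill_viridis_c(name = "Test AUC") +
    ggplot2::labs(x = "Clinical branch", y = "Imaging branch") +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @inheritParams roc_auc
#' @return a ggplot object.
#' @export
plot_roc <- function(probabilities, labels) {
  pts <- roc_points(probabilities, labels)
  auc <- roc_auc(probabilities, labels)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(x = "1 - Specificity", y = "Sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", auc)) +
    ggplot2::theme_minimal()
}
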