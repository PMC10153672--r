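CLASSIFIER_KINDS <- c("lr", "rf", "svm", "xgb")

kind_label <- function(kind) {
  c(lr = "LR", rf = "RF", svm = "SVM", xgb = "XGBoost")[kind]
}

#' Split a cohort into training and test sets
#'
#' Random 4:1-style split: `round(n * ratio)` cases go to training. The
#' split is deterministic per seed; stratified mode preserves class
#' fractions within rounding. `train_size` overrides the rounded size
#' (useful when an external split of a given size must be matched).
#'
#' @param cases data frame with `case_id` and `label` columns (or a
#'   character vector of ids with `labels` supplied separately).
#' @param ratio training fraction, strictly in (0, 1).
#' @param seed integer seed.
#' @param stratified preserve class fractions within rounding.
#' @param train_size optional explicit training-set size.
#' @param labels labels when `cases` is a bare id vector.
#' @return list with character vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_cohort <- function(cases, ratio = 0.8, seed = 1L, stratified = FALSE,
                         train_size = NULL, labels = NULL) {
  if (is.data.frame(cases)) {
    ids <- cases$case_id
    labels <- cases$label
  } else {
    ids <- cases
  }
  n <- length(ids)
  if (n < 5) stop("cohort too small: need at least 5 cases", call. = FALSE)
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)", call. = FALSE)
  set.seed(seed)
  if (stratified && !is.null(labels)) {
    tr_idx <- unlist(lapply(unique(labels), function(l) {
      idx <- which(labels == l)
      sample(idx, round(length(idx) * ratio))
    }))
  } else {
    n_train <- if (is.null(train_size)) round(n * ratio) else train_size
    tr_idx <- sample.int(n, n_train)
  }
  if (!is.null(train_size) && stratified)
    tr_idx <- tr_idx[seq_len(min(train_size, length(tr_idx)))]
  list(train = ids[sort(tr_idx)], test = ids[sort(setdiff(seq_len(n), tr_idx))])
}

#' Fit / apply a retained-variance PCA projection
#'
#' Centers by the training mean and retains the smallest number of
#' principal components whose cumulative explained variance reaches
#' `threshold`. `apply_pca()` projects any matrix with matching columns
#' using the stored training mean and components (no re-fitting).
#'
#' @param x numeric matrix or data frame of training rows (>= 2 rows).
#' @param threshold retained-variance threshold in (0, 1].
#' @return `fit_pca()`: object of class `pca_projection` with `center`,
#'   `rotation`, `sdev`, `n_components`; `apply_pca()`: the projected
#'   matrix (columns `PC1..PCn`).
#' @export
fit_pca <- function(x, threshold = 0.95) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 training rows", call. = FALSE)
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  cum <- cumsum(pr$sdev^2) / sum(pr$sdev^2)
  ncomp <- which(cum >= threshold - 1e-12)[1]
  structure(list(center = pr$center, rotation = pr$rotation, sdev = pr$sdev,
                 threshold = threshold, n_components = ncomp),
            class = "pca_projection")
}

#' @rdname fit_pca
#' @param proj a fitted `pca_projection`.
#' @param n_components override for the number of retained components.
#' @export
apply_pca <- function(proj, x, n_components = proj$n_components) {
  x <- as.matrix(x)
  if (ncol(x) != length(proj$center))
    stop("column mismatch: matrix does not match the fitted projection",
         call. = FALSE)
  sweep(x, 2, proj$center) %*% proj$rotation[, seq_len(n_components),
                                             drop = FALSE]
}

#' Fit a base classifier branch
#'
#' One of the four base models: logistic regression (`"lr"`), random
#' forest (`"rf"`), RBF-kernel SVM with Platt-scaled probabilities
#' (`"svm"`) or gradient-boosted trees (`"xgb"`). All emit class-1
#' probabilities and are deterministic per seed. Documented defaults:
#' RF 500 trees; SVM cost 1, radial kernel; XGBoost 100 rounds, depth 3,
#' eta 0.1; LR unpenalised. A training matrix in which no feature varies
#' degenerates, for every kind, to the class-prior predictor (constant
#' probability `mean(y)`).
#'
#' @param x numeric feature matrix or data frame (training rows).
#' @param y binary 0/1 labels (both classes must be present).
#' @param kind one of `"lr"`, `"rf"`, `"svm"`, `"xgb"`.
#' @param seed integer seed for the stochastic learners.
#' @return object of class `branch_fit`.
#' @export
fit_branch <- function(x, y, kind = c("lr", "rf", "svm", "xgb"), seed = 1L) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (length(unique(y)) < 2)
    stop("degenerate labels: a single class in the training set",
         call. = FALSE)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (all(apply(x, 2, function(cc) length(unique(cc))) == 1)) {
    # no feature varies: every learner degenerates to the class prior
    return(structure(list(kind = kind, model = NULL, prior = mean(y),
                          n_features = ncol(x), seed = seed),
                     class = "branch_fit"))
  }
  set.seed(seed)
  model <- switch(kind,
    lr = {
      df <- data.frame(.y = y, x)
      suppressWarnings(stats::glm(.y ~ ., data = df,
                                  family = stats::binomial()))
    },
    rf = randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                    ntree = 500),
    svm = e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                     cost = 1, probability = TRUE),
    xgb = xgboost::xgb.train(
      params = list(max_depth = 3, eta = 0.1, objective = "binary:logistic",
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = 100, verbose = 0))
  structure(list(kind = kind, model = model, n_features = ncol(x),
                 seed = seed), class = "branch_fit")
}

#' @rdname fit_branch
#' @param branch a fitted `branch_fit`.
#' @return `predict_branch()`: numeric vector of class-1 probabilities in
#'   `[0, 1]`.
#' @export
predict_branch <- function(branch, x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (is.null(branch$model)) return(rep(branch$prior, nrow(x)))
  p <- switch(branch$kind,
    lr = {
      df <- data.frame(x)
      as.numeric(stats::predict(branch$model, newdata = df,
                                type = "response"))
    },
    rf = stats::predict(branch$model, x, type = "prob")[, "1"],
    svm = {
      pr <- stats::predict(branch$model, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    xgb = stats::predict(branch$model,
                         xgboost::xgb.DMatrix(x, nthread = 1)))
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Fuse imaging and clinical probabilities
#'
#' Weighted late fusion: `w * p_imaging + (1 - w) * p_clinical`.
#'
#' @param p_imaging,p_clinical equal-length probability vectors.
#' @param w imaging weight in `[0, 1]`.
#' @return fused probabilities in `[0, 1]`.
#' @export
fuse_probs <- function(p_imaging, p_clinical, w = 0.5) {
  if (length(p_imaging) != length(p_clinical))
    stop("length mismatch between branch probabilities", call. = FALSE)
  if (w < 0 || w > 1) stop("fusion weight must lie in [0, 1]", call. = FALSE)
  w * p_imaging + (1 - w) * p_clinical
}

# Encode clinical covariates: meno stays binary, cN/cT/cTNM ordinal
# integers, age and size standardised with the training statistics.
encode_clinical <- function(clinical, scaling = NULL) {
  X <- cbind(age = clinical$age, size_cm = clinical$size_cm,
             meno = clinical$meno, cN = clinical$cN, cT = clinical$cT,
             cTNM = clinical$cTNM)
  if (is.null(scaling)) {
    scaling <- list(
      center = c(age = mean(X[, "age"]), size_cm = mean(X[, "size_cm"])),
      scale = c(age = stats::sd(X[, "age"]), size_cm = stats::sd(X[, "size_cm"])))
    scaling$scale[scaling$scale == 0 | is.na(scaling$scale)] <- 1
  }
  for (v in c("age", "size_cm"))
    X[, v] <- (X[, v] - scaling$center[v]) / scaling$scale[v]
  list(x = X, scaling = scaling)
}

feature_matrix <- function(features) {
  as.matrix(features[, setdiff(names(features), c("case_id", "label")),
                     drop = FALSE])
}

#' Fit the two-branch fusion model
#'
#' The imaging branch standardises the dynamic feature columns (training
#' statistics), projects them with PCA retaining `pca_threshold` cumulative
#' variance, and fits the chosen base classifier. The clinical branch
#' encodes the covariates (age and lesion size standardised on training
#' rows, menopause binary, cN/cT/cTNM ordinal) and fits its own base
#' classifier. Prediction averages the branch probabilities with weight
#' `w` and thresholds at `tau`. All fitted statistics (scaling, PCA,
#' classifiers) depend only on the training rows passed here.
#'
#' @param features tibble of dynamic features: `case_id` plus numeric
#'   columns (training rows).
#' @param clinical tibble with `case_id`, the clinical covariates and
#'   `label` (training rows, matched to `features` by `case_id`).
#' @param imaging_kind,clinical_kind base classifier kinds (see
#'   [fit_branch()]).
#' @param w fusion weight on the imaging branch.
#' @param tau decision threshold on the fused probability.
#' @param pca_threshold retained-variance threshold for the imaging PCA.
#' @param seed integer seed.
#' @return object of class `fusion_model`.
#' @export
fit_fusion_model <- function(features, clinical,
                             imaging_kind = "xgb", clinical_kind = "lr",
                             w = 0.5, tau = 0.5, pca_threshold = 0.95,
                             seed = 1L) {
  stopifnot(all(features$case_id %in% clinical$case_id))
  clinical <- clinical[match(features$case_id, clinical$case_id), ]
  y <- clinical$label
  X <- feature_matrix(features)
  keep <- which(apply(X, 2, stats::sd) > 0)
  mu <- colMeans(X[, keep, drop = FALSE])
  sg <- apply(X[, keep, drop = FALSE], 2, stats::sd)
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, mu), 2, sg, "/")
  proj <- fit_pca(Z, threshold = pca_threshold)
  Zp <- apply_pca(proj, Z)
  img <- fit_branch(Zp, y, imaging_kind, seed = seed)
  enc <- encode_clinical(clinical)
  cln <- fit_branch(enc$x, y, clinical_kind, seed = seed)
  structure(list(
    imaging = list(keep = keep, center = mu, scale = sg, proj = proj,
                   fit = img),
    clinical = list(scaling = enc$scaling, fit = cln),
    w = w, tau = tau, n_train = length(y), seed = seed
  ), class = "fusion_model")
}

predict_imaging <- function(fm, features) {
  X <- feature_matrix(features)
  Z <- sweep(sweep(X[, fm$imaging$keep, drop = FALSE], 2,
                   fm$imaging$center), 2, fm$imaging$scale, "/")
  predict_branch(fm$imaging$fit, apply_pca(fm$imaging$proj, Z))
}

#' Predict with a fitted fusion model
#'
#' @param object a `fusion_model`.
#' @param features dynamic-feature tibble (`case_id` + feature columns).
#' @param clinical clinical tibble matched by `case_id` (a `label` column,
#'   if present, is carried through).
#' @param ... unused.
#' @return tibble with `case_id`, optional `label`, `p_imaging`,
#'   `p_clinical`, `p_fused` and the binary `call` at the model's
#'   threshold.
#' @export
predict.fusion_model <- function(object, features, clinical, ...) {
  clinical <- clinical[match(features$case_id, clinical$case_id), ]
  p_img <- predict_imaging(object, features)
  enc <- encode_clinical(clinical, scaling = object$clinical$scaling)
  p_cln <- predict_branch(object$clinical$fit, enc$x)
  p <- fuse_probs(p_img, p_cln, object$w)
  out <- tibble::tibble(case_id = features$case_id)
  if ("label" %in% names(clinical)) out$label <- clinical$label
  out$p_imaging <- p_img
  out$p_clinical <- p_cln
  out$p_fused <- p
  out$call <- as.integer(p >= object$tau)
  out
}

#' Tidy a fitted fusion model's branch structure
#' @param x a `fusion_model`.
#' @param ... unused.
#' @method tidy fusion_model
#' @export
tidy.fusion_model <- function(x, ...) {
  tibble::tibble(
    branch = c("imaging", "clinical"),
    kind = c(x$imaging$fit$kind, x$clinical$fit$kind),
    n_features = c(length(x$imaging$keep), x$clinical$fit$n_features),
    n_components = c(x$imaging$proj$n_components, NA_integer_))
}

#' One-row summary of a fitted fusion model
#' @param x a `fusion_model`.
#' @param ... unused.
#' @method glance fusion_model
#' @export
glance.fusion_model <- function(x, ...) {
  tibble::tibble(
    imaging_kind = x$imaging$fit$kind,
    clinical_kind = x$clinical$fit$kind,
    n_train = x$n_train,
    n_components = x$imaging$proj$n_components,
    pca_threshold = x$imaging$proj$threshold,
    w = x$w, tau = x$tau)
}

branch_probs_all <- function(features_tr, clinical_tr, features_te,
                             clinical_te, kinds, pca_threshold, seed) {
  y_tr <- clinical_tr$label[match(features_tr$case_id, clinical_tr$case_id)]
  X <- feature_matrix(features_tr)
  keep <- which(apply(X, 2, stats::sd) > 0)
  mu <- colMeans(X[, keep, drop = FALSE])
  sg <- apply(X[, keep, drop = FALSE], 2, stats::sd)
  std <- function(M) sweep(sweep(M[, keep, drop = FALSE], 2, mu), 2, sg, "/")
  proj <- fit_pca(std(X), threshold = pca_threshold)
  Ztr <- apply_pca(proj, std(X))
  Zte <- apply_pca(proj, std(feature_matrix(features_te)))
  ord_cl <- match(features_tr$case_id, clinical_tr$case_id)
  enc_tr <- encode_clinical(clinical_tr[ord_cl, ])
  enc_te <- encode_clinical(
    clinical_te[match(features_te$case_id, clinical_te$case_id), ],
    scaling = enc_tr$scaling)
  img <- purrr::map(stats::setNames(kinds, kinds), function(k) {
    b <- fit_branch(Ztr, y_tr, k, seed = seed)
    list(train = predict_branch(b, Ztr), test = predict_branch(b, Zte))
  })
  cln <- purrr::map(stats::setNames(kinds, kinds), function(k) {
    b <- fit_branch(enc_tr$x, y_tr, k, seed = seed)
    list(train = predict_branch(b, enc_tr$x),
         test = predict_branch(b, enc_te$x))
  })
  list(imaging = img, clinical = cln)
}

#' Run the 4 x 4 base-model selection grid
#'
#' Fits each of the four base classifiers as an imaging branch (PCA on the
#' dynamic features) and as a clinical branch on the training cohort, then
#' evaluates on training and test cohorts every fused pairing (16 models)
#' together with the 4 imaging-only and 4 clinical-only models. The best
#' fused pair is selected by test AUC, ties broken by higher Youden index
#' and then lexicographic kind names.
#'
#' @param features_train,features_test dynamic-feature tibbles.
#' @param clinical_train,clinical_test clinical tibbles with `label`.
#' @param kinds classifier kinds to cross (default all four).
#' @param w,tau fusion weight and decision threshold.
#' @param pca_threshold imaging-branch retained-variance threshold.
#' @param seed integer seed.
#' @return tibble of class `model_grid`: one row per model (16 fused + 4
#'   imaging-only + 4 clinical-only), with train/test AUC, ACC, SEN, SPC
#'   and YI columns; the winning pair is in `attr(, "best")`.
#' @export
run_model_grid <- function(features_train, clinical_train, features_test,
                           clinical_test, kinds = CLASSIFIER_KINDS,
                           w = 0.5, tau = 0.5, pca_threshold = 0.95,
                           seed = 1L) {
  pr <- branch_probs_all(features_train, clinical_train, features_test,
                         clinical_test, kinds, pca_threshold, seed)
  y_tr <- clinical_train$label[match(features_train$case_id,
                                     clinical_train$case_id)]
  y_te <- clinical_test$label[match(features_test$case_id,
                                    clinical_test$case_id)]
  row_for <- function(branch, ik, ck, p_tr, p_te) {
    m_tr <- evaluate_predictions(p_tr, y_tr, tau = tau)
    m_te <- evaluate_predictions(p_te, y_te, tau = tau)
    tibble::tibble(branch = branch,
                   imaging_kind = ik, clinical_kind = ck,
                   model = if (branch == "fused")
                     paste(kind_label(ik), kind_label(ck), sep = "+")
                   else kind_label(if (branch == "imaging") ik else ck),
                   auc_train = m_tr$auc, acc_train = m_tr$acc,
                   sen_train = m_tr$sen, spc_train = m_tr$spc,
                   yi_train = m_tr$yi,
                   auc_test = m_te$auc, acc_test = m_te$acc,
                   sen_test = m_te$sen, spc_test = m_te$spc,
                   yi_test = m_te$yi)
  }
  rows <- list()
  for (ik in kinds) for (ck in kinds) {
    rows[[length(rows) + 1L]] <- row_for(
      "fused", ik, ck,
      fuse_probs(pr$imaging[[ik]]$train, pr$clinical[[ck]]$train, w),
      fuse_probs(pr$imaging[[ik]]$test, pr$clinical[[ck]]$test, w))
  }
  for (k in kinds) {
    rows[[length(rows) + 1L]] <- row_for("imaging", k, NA_character_,
                                         pr$imaging[[k]]$train,
                                         pr$imaging[[k]]$test)
    rows[[length(rows) + 1L]] <- row_for("clinical", NA_character_, k,
                                         pr$clinical[[k]]$train,
                                         pr$clinical[[k]]$test)
  }
  grid <- dplyr::bind_rows(rows)
  fused <- grid[grid$branch == "fused", ]
  ord <- order(-fused$auc_test, -fused$yi_test, fused$imaging_kind,
               fused$clinical_kind)
  best <- fused[ord[1], c("imaging_kind", "clinical_kind", "auc_test")]
  attr(grid, "best") <- as.list(best)
  class(grid) <- c("model_grid", class(grid))
  grid
}
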