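test_that("cohort splitting honours sizes, determinism and stratification", {
  cases <- tibble::tibble(case_id = sprintf("c%03d", 1:10),
                          label = rep(0:1, 5))
  sp <- split_cohort(cases, ratio = 0.8, seed = 3)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), cases$case_id)
  expect_identical(sp, split_cohort(cases, ratio = 0.8, seed = 3))
  big <- tibble::tibble(case_id = sprintf("c%03d", 1:445),
                        label = rep_len(0:1, 445))
  expect_length(split_cohort(big, 0.8, seed = 1)$train, round(445 * 0.8))
  expect_length(split_cohort(big, 0.8, seed = 1, train_size = 357)$train, 357)
  st <- split_cohort(cases, 0.8, seed = 2, stratified = TRUE)
  expect_equal(sum(cases$label[cases$case_id %in% st$train]), 4)
  expect_error(split_cohort(cases[1:4, ]), "too small")
})

test_that("PCA retains the right rank and preserves geometry when complete", {
  set.seed(5)
  basis <- qr.Q(qr(matrix(rnorm(25), 5, 5)))[, 1:2]
  x <- matrix(rnorm(80), 40, 2) %*% t(basis)  # rank 2 by construction
  proj <- fit_pca(x, threshold = 0.95)
  expect_equal(proj$n_components, 2)
  # orthonormal components
  rot <- proj$rotation[, 1:2]
  expect_equal(unname(t(rot) %*% rot), diag(2), tolerance = 1e-8)
  # all components retained: pairwise distances preserved
  xf <- matrix(rnorm(60), 20, 3)
  pf <- fit_pca(xf, threshold = 1.0)
  z <- apply_pca(pf, xf, n_components = 3)
  expect_equal(as.matrix(dist(z)), as.matrix(dist(xf)), tolerance = 1e-8)
  expect_error(apply_pca(proj, matrix(0, 2, 7)), "column mismatch")
})

test_that("every base classifier separates blobs and stays honest on noise", {
  toy <- toy_blobs(n = 200, sep = 6, seed = 1)
  for (k in c("lr", "rf", "svm", "xgb")) {
    b <- fit_branch(toy$x, toy$y, k, seed = 1)
    p <- predict_branch(b, toy$x)
    expect_true(all(p >= 0 & p <= 1))
    expect_gte(mean((p >= 0.5) == toy$y), 0.95)
  }
  # permuted labels: cross-validated AUC near chance (averaged over
  # permutations so the check reflects the method, not one shuffle)
  set.seed(9)
  folds <- rep_len(1:5, 200)
  for (k in c("lr", "xgb")) {
    aucs <- vapply(1:3, function(rep_i) {
      yperm <- sample(toy$y)
      p_cv <- numeric(200)
      for (f in 1:5) {
        b <- fit_branch(toy$x[folds != f, ], yperm[folds != f], k, seed = f)
        p_cv[folds == f] <- predict_branch(b,
                                           toy$x[folds == f, , drop = FALSE])
      }
      roc_auc(p_cv, yperm)
    }, numeric(1))
    expect_lt(abs(mean(aucs) - 0.5), 0.1)
  }
  # identical rows with conflicting labels: no infinite confidence
  xdup <- matrix(1, 20, 3)
  ydup <- rep(0:1, 10)
  for (k in c("lr", "rf", "svm", "xgb")) {
    p <- predict_branch(fit_branch(xdup, ydup, k, seed = 1), xdup)
    expect_true(all(p > 0 & p < 1))
  }
  expect_error(fit_branch(toy$x, rep(1, 200), "lr"), "degenerate labels")
})

test_that("probability fusion is the stated convex combination", {
  expect_equal(fuse_probs(0.6, 0.8, w = 0.5), 0.7)
  p1 <- runif(10); p2 <- runif(10)
  expect_equal(fuse_probs(p1, p2, w = 1), p1)
  expect_equal(fuse_probs(p1, p2, w = 0), p2)
  expect_true(all(fuse_probs(p1, p2, 0.3) >= 0 & fuse_probs(p1, p2, 0.3) <= 1))
  expect_error(fuse_probs(p1, p2[1:5], 0.5), "length mismatch")
  expect_error(fuse_probs(p1, p2, 1.2), "\\[0, 1\\]")
  # a constant branch cannot change the other branch's ranking at w extremes
  pc <- rep(0.5, 10)
  expect_equal(order(fuse_probs(p1, pc, 1)), order(p1))
})

# compact synthetic feature + clinical fixture for the fusion model
fusion_fixture <- function(n = 60, seed = 31, informative_clinical = TRUE) {
  set.seed(seed)
  y <- rep(0:1, n / 2)
  x <- cbind(matrix(rnorm(n * 8), n, 8) + 2.5 * y,
             matrix(rnorm(n * 12), n, 12))
  colnames(x) <- paste0("v", 1:20)
  feats <- dplyr::bind_cols(tibble::tibble(case_id = sprintf("c%02d", 1:n)),
                            tibble::as_tibble(x))
  clin <- tibble::tibble(
    case_id = feats$case_id,
    age = round(rnorm(n, 52, 10)),
    size_cm = pmax(rnorm(n, 2.3 + informative_clinical * 0.8 * y, 0.8), 0.3),
    meno = rbinom(n, 1, 0.5),
    cN = sample(0:2, n, TRUE, c(0.7, 0.25, 0.05)),
    cT = sample(1:3, n, TRUE, c(0.5, 0.45, 0.05)),
    cTNM = sample(1:3, n, TRUE, c(0.4, 0.55, 0.05)),
    label = y)
  list(features = feats, clinical = clin)
}

test_that("fusion model fits, predicts in range, and is seed-deterministic", {
  fx <- fusion_fixture()
  fm <- fit_fusion_model(fx$features, fx$clinical, "xgb", "lr", seed = 2)
  pred <- predict(fm, fx$features, fx$clinical)
  expect_true(all(pred$p_fused >= 0 & pred$p_fused <= 1))
  expect_equal(pred$p_fused, 0.5 * pred$p_imaging + 0.5 * pred$p_clinical)
  expect_equal(pred$call, as.integer(pred$p_fused >= 0.5))
  fm2 <- fit_fusion_model(fx$features, fx$clinical, "xgb", "lr", seed = 2)
  pred2 <- predict(fm2, fx$features, fx$clinical)
  expect_equal(pred, pred2)
  td <- tidy(fm)
  expect_equal(td$branch, c("imaging", "clinical"))
  gl <- glance(fm)
  expect_equal(gl$imaging_kind, "xgb")
  expect_equal(gl$n_train, 60)
})

test_that("fitted branches depend only on training rows (no leakage)", {
  fx <- fusion_fixture(n = 40, seed = 7)
  tr <- 1:30; te <- 31:40
  fit_once <- function(test_noise) {
    f <- fx$features; c2 <- fx$clinical
    f[te, -1] <- f[te, -1] + test_noise
    c2$age[te] <- c2$age[te] + test_noise
    fm <- fit_fusion_model(f[tr, ], c2[tr, ], "xgb", "lr", seed = 5)
    predict(fm, fx$features[tr, ], fx$clinical[tr, ])
  }
  expect_identical(fit_once(0), fit_once(100))
})

test_that("the 4x4 grid has 16 fused + 8 single-branch rows and a sane winner", {
  fx <- fusion_fixture(n = 50, seed = 13)
  tr <- 1:40; te <- 41:50
  grid <- run_model_grid(fx$features[tr, ], fx$clinical[tr, ],
                         fx$features[te, ], fx$clinical[te, ], seed = 3)
  expect_equal(sum(grid$branch == "fused"), 16)
  expect_equal(sum(grid$branch == "imaging"), 4)
  expect_equal(sum(grid$branch == "clinical"), 4)
  best <- attr(grid, "best")
  expect_true(best$imaging_kind %in% c("lr", "rf", "svm", "xgb"))
  expect_equal(best$auc_test, max(grid$auc_test[grid$branch == "fused"]))
  # determinism
  grid2 <- run_model_grid(fx$features[tr, ], fx$clinical[tr, ],
                          fx$features[te, ], fx$clinical[te, ], seed = 3)
  expect_equal(as.data.frame(grid), as.data.frame(grid2))
  # YI identity on every row
  expect_equal(grid$yi_test, grid$sen_test + grid$spc_test - 1)
})

test_that("with uninformative clinical data fusion never falls below clinical-only", {
  fx <- fusion_fixture(n = 60, seed = 17, informative_clinical = FALSE)
  tr <- 1:48; te <- 49:60
  grid <- run_model_grid(fx$features[tr, ], fx$clinical[tr, ],
                         fx$features[te, ], fx$clinical[te, ], seed = 11)
  fused <- grid[grid$branch == "fused", ]
  cln <- grid[grid$branch == "clinical", ]
  for (i in seq_len(nrow(fused))) {
    expect_gte(fused$auc_test[i],
               cln$auc_test[cln$clinical_kind == fused$clinical_kind[i]])
  }
})
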