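constant_spec <- function(level) {
  list(fit = function(x, y) levels(y),
       predict = function(model, x)
         factor(rep(model[level], nrow(x)), levels = model))
}

test_that("five-group rotation accuracy matches a manual tally", {
  d <- blob_dataset(n_per_class = 10, sep = 6, seed = 1)

  rep_const <- five_fold_rotation(d, constant_spec(1))
  expect_equal(rep_const$overall, 1 / 3)
  expect_equal(unname(rep_const$per_class), c(1, 0, 0))

  # oracle model: memorizes nothing, predicts from the blob geometry
  # (class signal lives in standardized columns 1-5 and 6-10)
  oracle_spec <- list(
    fit = function(x, y) NULL,
    predict = function(model, x) {
      idx <- apply(x, 1, function(v) {
        a <- mean(v[1:5]); b <- mean(v[6:10])
        which.max(c(-a - b, a, b))
      })
      factor(c("normal", "cirrhosis", "cancer")[idx],
             levels = c("normal", "cirrhosis", "cancer"))
    })
  rep_oracle <- five_fold_rotation(d, oracle_spec)
  expect_gte(rep_oracle$overall, 0.95)

  # pooled confusion-matrix trace equals the overall accuracy
  expect_equal(sum(diag(rep_oracle$confusion)) / sum(rep_oracle$confusion),
               rep_oracle$overall)

  # manual recount on a <= 30-sample dataset
  small <- blob_dataset(n_per_class = 6, sep = 6, seed = 2)
  spec <- svm_model_spec(cost = 10, gamma = 0.05)
  cv <- immunotexture:::cv_accuracy(small, spec)
  hits <- 0L
  for (f in 0:4) {
    te <- small$fold_id == f
    hits <- hits + sum(cv$predictions[te] == small$labels[te])
  }
  expect_equal(cv$overall, hits / length(small$labels))
})

test_that("fold construction is stratified and validated", {
  d <- blob_dataset(n_per_class = 10, seed = 3)
  for (f in 0:4)
    expect_setequal(as.character(unique(d$labels[d$fold_id == f])),
                    c("normal", "cirrhosis", "cancer"))
  bad_folds <- c(rep(0L, 15), rep(1L, 15))
  expect_error(labeled_dataset(d$features, d$labels, bad_folds),
               "every class")
})

test_that("grid-searched SVM baseline separates blobs and counts fits", {
  d <- blob_dataset(n_per_class = 10, sep = 8, seed = 4)
  rep <- svm_grid_baseline(d, grid_size = 5)
  expect_gte(rep$overall, 0.95)
  expect_equal(rep$evaluations, 5 * 5 * 5)  # |grid| x 5 rotations

  # permuted labels drop to chance (mean over permutation seeds; a
  # fixed model spec avoids the optimistic bias of re-tuning the grid
  # on null data)
  null_acc <- vapply(1:8, function(s) {
    set.seed(100 + s)
    perm <- labeled_dataset(d$features, sample(d$labels))
    five_fold_rotation(perm, svm_model_spec(1, 0.1))$overall
  }, 0)
  expect_lt(abs(mean(null_acc) - 1 / 3), 0.1)
})

test_that("prototype immune classifier works and reduces to nearest centroid", {
  d <- blob_dataset(n_per_class = 10, sep = 8, seed = 5)
  set.seed(1)
  rep <- immune_classifier_baseline(d)
  expect_gte(rep$overall, 0.9)
  set.seed(1)
  rep2 <- immune_classifier_baseline(d)
  expect_identical(rep$overall, rep2$overall)

  # 1 prototype, no refinement = exact nearest-centroid
  set.seed(2)
  rep_nc <- immune_classifier_baseline(d, n_prototypes = 1, passes = 0)
  nc_oracle <- list(
    fit = function(x, y) {
      t(vapply(levels(y), function(cl)
        colMeans(x[y == cl, , drop = FALSE]), numeric(ncol(x))))
    },
    predict = function(model, x) {
      d2 <- apply(model, 1, function(ctr) colSums((t(x) - ctr)^2))
      factor(rownames(model)[apply(d2, 1, which.min)],
             levels = rownames(model))
    })
  rep_oracle <- five_fold_rotation(d, nc_oracle)
  expect_equal(rep_nc$overall, rep_oracle$overall)
  expect_equal(rep_nc$per_class, rep_oracle$per_class)
})

test_that("PCA baseline projects on training folds and keeps full-rank parity", {
  # enough samples that training folds span all 30 dimensions
  d <- blob_dataset(n_per_class = 15, sep = 8, seed = 7)
  rep_full <- pca_svm_baseline(d, n_components = 30, cost = 10, gamma = 0.05)
  rep_svm <- immunotexture:::cv_accuracy(d, svm_model_spec(10, 0.05))
  # full-rank PCA is an orthogonal rotation: RBF distances unchanged
  expect_equal(rep_full$overall, rep_svm$overall, tolerance = 1e-6)

  # one latent class axis expressed in six correlated columns: a single
  # principal component suffices
  ax <- axis_blob_dataset(n_per_class = 15, sep = 6, seed = 11)
  rep1 <- pca_svm_baseline(ax, n_components = 1, cost = 10, gamma = 0.5)
  expect_gte(rep1$overall, 0.9)
  expect_error(pca_svm_baseline(d, 31), "between")
})

test_that("PCA reduction keeps exactly n_components columns", {
  d <- blob_dataset(n_per_class = 10, seed = 8)
  seen_cols <- NULL
  spy <- list(fit = function(x, y) { seen_cols <<- ncol(x); levels(y) },
              predict = function(model, x)
                factor(rep(model[1], nrow(x)), levels = model))
  transform <- function(train, test) {
    pc <- stats::prcomp(train, center = FALSE, scale. = FALSE)
    list(train = train %*% pc$rotation[, 1:4], test = test %*% pc$rotation[, 1:4])
  }
  immunotexture:::cv_accuracy(d, spy, transform = transform)
  expect_equal(seen_cols, 4)
})

test_that("test-fold perturbations never leak into fitted preprocessing", {
  d <- blob_dataset(n_per_class = 10, seed = 9)
  seen_train <- list()
  spy <- list(
    fit = function(x, y) { seen_train[[length(seen_train) + 1]] <<- x
                           levels(y) },
    predict = function(model, x)
      factor(rep(model[1], nrow(x)), levels = model))
  immunotexture:::cv_accuracy(d, spy)
  base_train <- seen_train

  # corrupt every test fold's rows wildly; training views must not move
  seen_train <- list()
  d2 <- d
  for (f in 0:4) {
    rows <- d2$fold_id == f
    d2$features[rows, ] <- d2$features[rows, ] * 1e3 + 500
    seen_train <- list()
    immunotexture:::cv_accuracy(d2, spy)
    expect_identical(seen_train[[f + 1]], base_train[[f + 1]])
    d2 <- d  # restore
  }
})

test_that("algorithm comparison emits the expected table", {
  d <- blob_dataset(n_per_class = 10, sep = 8, seed = 10)
  cfg <- ia_config(seed = 1, max_generations = 2, target_affinity = 0.99)
  tab <- compare_algorithms(d, cfg, grid_size = 3, pca_components = 5,
                            seed = 1)
  expect_setequal(tab$algorithm,
                  c("immune", "svm", "optimized_immune", "pca_svm"))
  expect_true(all(c("evaluations", "accuracy", "acc_normal",
                    "acc_cirrhosis", "acc_cancer") %in% names(tab)))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  tab2 <- compare_algorithms(d, cfg, grid_size = 3, pca_components = 5,
                             seed = 1)
  expect_equal(as.data.frame(tab)[names(tab) != "evaluations"],
               as.data.frame(tab2)[names(tab2) != "evaluations"],
               ignore_attr = TRUE)
  expect_equal(tab$evaluations, tab2$evaluations)
})
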