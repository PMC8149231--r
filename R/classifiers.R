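CLASS_LEVELS <- c("normal", "cirrhosis", "cancer")

#' Labeled texture-feature dataset
#'
#' Container for the N x 30 feature matrix, tissue-class labels and the
#' five-group rotation assignment: samples are split into five groups,
#' each used once for testing while the other four train the classifier.
#'
#' @param features numeric matrix (or data.frame) with named feature
#'   columns; no missing values.
#' @param labels factor or character in `normal`, `cirrhosis`, `cancer`
#'   (encoded 0/1/2 in CSVs).
#' @param fold_id optional integer fold assignment in 0..4; when absent,
#'   folds are assigned stratified by class using the current RNG.
#' @return object of class `labeled_dataset` with `features`, `labels`,
#'   `fold_id`.
#' @export
labeled_dataset <- function(features, labels, fold_id = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (anyNA(features)) stop("feature matrix contains missing values")
  labels <- if (is.factor(labels)) droplevels(labels)
            else factor(labels, levels = intersect(CLASS_LEVELS, unique(labels)))
  if (anyNA(labels)) stop("labels must be in {normal, cirrhosis, cancer}")
  if (length(labels) != nrow(features)) stop("labels/features length mismatch")
  if (is.null(fold_id)) fold_id <- assign_folds(labels)
  fold_id <- as.integer(fold_id)
  if (length(fold_id) != nrow(features) || any(fold_id < 0L | fold_id > 4L))
    stop("`fold_id` must give each sample a fold in 0..4")
  for (f in 0:4) {
    present <- unique(labels[fold_id == f])
    if (length(present) < nlevels(labels))
      stop("every fold must contain every class (stratify the folds)")
  }
  structure(list(features = features, labels = labels, fold_id = fold_id),
            class = "labeled_dataset")
}

#' Stratified five-fold assignment
#'
#' @param labels class factor.
#' @return integer vector of folds 0..4, each class spread evenly.
#' @export
assign_folds <- function(labels) {
  fold <- integer(length(labels))
  for (cl in levels(factor(labels))) {
    idx <- which(labels == cl)
    fold[idx] <- (sample(seq_along(idx)) - 1L) %% 5L
  }
  fold
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d samples x %d features (%s)\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%s=%d", levels(x$labels),
                            as.integer(table(x$labels))), collapse = ", ")))
  invisible(x)
}

#' RBF-SVM model specification
#'
#' A model spec is a pair of closures (`fit`, `predict`) consumed by
#' [five_fold_rotation()]; this one wraps [e1071::svm()] with a radial
#' kernel and one-vs-one multiclass handling.
#'
#' @param cost SVM regularization parameter C.
#' @param gamma RBF kernel width r.
#' @return list with `fit(x, y)` and `predict(model, x)`.
#' @export
svm_model_spec <- function(cost = 1, gamma = 0.1) {
  list(
    fit = function(x, y)
      e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
                 scale = FALSE),
    predict = function(model, x) stats::predict(model, x))
}

# standardize train columns to zero mean / unit sd; apply to test.
# Statistics come from the training rows only (no test-fold leakage).
.standardize <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sd, "/"),
       test = sweep(sweep(test, 2, mu), 2, sd, "/"),
       center = mu, scale = sd)
}

# core five-group rotation; columns restricts to a feature subset,
# transform optionally maps (train, test) -> list(train, test) after
# standardization (used for PCA)
cv_accuracy <- function(data, spec, columns = NULL, transform = NULL) {
  x <- data$features
  if (!is.null(columns)) x <- x[, columns, drop = FALSE]
  y <- data$labels
  hits <- logical(length(y))
  pred_all <- factor(rep(levels(y)[1], length(y)), levels = levels(y))
  fits <- 0L
  for (f in 0:4) {
    te <- data$fold_id == f
    st <- .standardize(x[!te, , drop = FALSE], x[te, , drop = FALSE])
    tr_x <- st$train; te_x <- st$test
    if (!is.null(transform)) {
      tt <- transform(tr_x, te_x)
      tr_x <- tt$train; te_x <- tt$test
    }
    model <- spec$fit(tr_x, y[!te])
    fits <- fits + 1L
    p <- spec$predict(model, te_x)
    pred_all[te] <- p
    hits[te] <- p == y[te]
  }
  per_class <- vapply(levels(y), function(cl) mean(hits[y == cl]), 0)
  list(overall = mean(hits), per_class = per_class,
       predictions = pred_all, fits = fits)
}

#' Five-group rotation evaluation
#'
#' Each of the five groups is held out in turn for testing while the
#' other four train the model; feature standardization is fitted on the
#' training groups only. Overall accuracy is the pooled fraction of
#' correctly recognized samples (equivalently the trace ratio of the
#' pooled confusion matrix).
#'
#' @param data a [labeled_dataset()].
#' @param spec a model spec (see [svm_model_spec()]).
#' @return object of class `eval_report`: `overall`, `per_class`
#'   (named accuracies), `evaluations` (model fits performed),
#'   `confusion` (pooled confusion matrix).
#' @export
five_fold_rotation <- function(data, spec) {
  cv <- cv_accuracy(data, spec)
  structure(list(overall = cv$overall, per_class = cv$per_class,
                 evaluations = cv$fits,
                 confusion = table(truth = data$labels,
                                   predicted = cv$predictions)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: overall accuracy %.4f (%d model fits)\n",
              x$overall, x$evaluations))
  print(round(x$per_class, 4))
  invisible(x)
}

#' Grid-searched plain SVM baseline
#'
#' Exhaustive log2-spaced (C, r) grid over the same search box as the
#' immune optimizer, all 30 features retained, each grid point scored by
#' the five-group rotation. The evaluation count is grid size x 5 fits,
#' the cost unit shared with the other algorithms.
#'
#' @param data a [labeled_dataset()].
#' @param grid_size points per axis (default 15).
#' @param c_bounds,r_bounds log2 search box (defaults match
#'   [ia_config()]).
#' @return an `eval_report` for the best grid point, with `best_C`,
#'   `best_gamma` attached and `evaluations` counting every SVM fit.
#' @export
svm_grid_baseline <- function(data, grid_size = 15L,
                              c_bounds = c(2^-5, 2^15),
                              r_bounds = c(2^-15, 2^3)) {
  cs <- 2^seq(log2(c_bounds[1]), log2(c_bounds[2]), length.out = grid_size)
  rs <- 2^seq(log2(r_bounds[1]), log2(r_bounds[2]), length.out = grid_size)
  best <- NULL; fits <- 0L
  for (C in cs) for (r in rs) {
    cv <- cv_accuracy(data, svm_model_spec(C, r))
    fits <- fits + cv$fits
    if (is.null(best) || cv$overall > best$cv$overall)
      best <- list(cv = cv, C = C, r = r)
  }
  structure(list(overall = best$cv$overall, per_class = best$cv$per_class,
                 evaluations = fits,
                 confusion = table(truth = data$labels,
                                   predicted = best$cv$predictions),
                 best_C = best$C, best_gamma = best$r),
            class = "eval_report")
}

#' Clonal-selection prototype classifier spec
#'
#' The stand-alone immune-algorithm classifier: each class is represented
#' by a small repertoire of prototype antibodies (feature vectors) whose
#' affinity for a sample is the negative Euclidean distance. Training
#' clonally expands and mutates the best-matching prototype of the true
#' class toward each training sample over a few passes; prediction is by
#' nearest prototype. This prototype form is a synthetic stand-in for an
#' unspecified reference classifier and is labeled as such.
#'
#' @param n_prototypes prototypes per class (default 3). The first
#'   prototype of each class starts at the class centroid, the rest at
#'   random training samples; with `n_prototypes = 1, passes = 0` the
#'   classifier reduces exactly to nearest-centroid.
#' @param n_clones clones of the best-matching prototype per update
#'   (default 5).
#' @param passes sweeps through the training data (default 3; 0 skips
#'   clonal refinement).
#' @param mutation_sd initial clone perturbation scale, decayed each pass
#'   (default 0.5; features are standardized, so this is in sd units).
#' @return a model spec for [five_fold_rotation()].
#' @export
immune_prototype_spec <- function(n_prototypes = 3L, n_clones = 5L,
                                  passes = 3L, mutation_sd = 0.5) {
  fit <- function(x, y) {
    protos <- list()
    for (cl in levels(y)) {
      idx <- which(y == cl)
      centroid <- colMeans(x[idx, , drop = FALSE])
      extra <- if (n_prototypes > 1L)
        idx[sample.int(length(idx), min(n_prototypes - 1L, length(idx)))]
      else integer(0)
      protos[[cl]] <- rbind(matrix(centroid, 1),
                            x[extra, , drop = FALSE])
    }
    for (pass in seq_len(passes)) {
      sd_now <- mutation_sd / pass
      ord <- sample(nrow(x))
      for (i in ord) {
        cl <- as.character(y[i])
        P <- protos[[cl]]
        d <- sqrt(rowSums(sweep(P, 2, x[i, ])^2))
        b <- which.min(d)
        # antigen-directed hypermutation: clones step part-way toward
        # the sample, plus isotropic noise that decays over passes
        steps <- stats::runif(n_clones, 0, 0.5)
        clones <- matrix(rep(P[b, ], n_clones), n_clones, byrow = TRUE)
        clones <- clones + steps * (matrix(rep(x[i, ], n_clones), n_clones,
                                           byrow = TRUE) - clones) +
          matrix(stats::rnorm(n_clones * ncol(x), 0, sd_now / 4), n_clones)
        cd <- sqrt(rowSums(sweep(clones, 2, x[i, ])^2))
        if (min(cd) < d[b]) P[b, ] <- clones[which.min(cd), ]
        protos[[cl]] <- P
      }
    }
    protos
  }
  predict <- function(model, x) {
    cls <- names(model)
    scores <- vapply(cls, function(cl) {
      P <- model[[cl]]
      apply(x, 1, function(v) min(sqrt(colSums((t(P) - v)^2))))
    }, numeric(nrow(x)))
    if (nrow(x) == 1L) scores <- matrix(scores, 1)
    factor(cls[apply(scores, 1, which.min)], levels = cls)
  }
  list(fit = fit, predict = predict)
}

#' Plain immune-algorithm classifier baseline
#'
#' Evaluates the clonal-selection prototype classifier
#' ([immune_prototype_spec()]) with the five-group rotation.
#'
#' @param data a [labeled_dataset()].
#' @param ... passed to [immune_prototype_spec()].
#' @return an `eval_report`.
#' @export
immune_classifier_baseline <- function(data, ...) {
  five_fold_rotation(data, immune_prototype_spec(...))
}

#' PCA + SVM baseline
#'
#' Dimensionality reduction before the SVM: principal components are
#' fitted on the training groups only (after standardization), both
#' train and test features are projected onto the leading
#' `n_components`, and the RBF-SVM is evaluated with the five-group
#' rotation.
#'
#' @param data a [labeled_dataset()].
#' @param n_components number of components, 1..30 (default 10).
#' @param cost,gamma SVM parameters.
#' @return an `eval_report`.
#' @export
pca_svm_baseline <- function(data, n_components = 10L, cost = 1, gamma = 0.1) {
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > ncol(data$features))
    stop("`n_components` must be between 1 and the feature count")
  transform <- function(train, test) {
    pc <- stats::prcomp(train, center = FALSE, scale. = FALSE)
    k <- min(n_components, ncol(pc$rotation))
    list(train = train %*% pc$rotation[, seq_len(k), drop = FALSE],
         test = test %*% pc$rotation[, seq_len(k), drop = FALSE])
  }
  cv <- cv_accuracy(data, svm_model_spec(cost, gamma), transform = transform)
  structure(list(overall = cv$overall, per_class = cv$per_class,
                 evaluations = cv$fits,
                 confusion = table(truth = data$labels,
                                   predicted = cv$predictions)),
            class = "eval_report")
}

#' Compare the classification algorithms
#'
#' Runs the plain immune prototype classifier, the grid-searched SVM,
#' the optimized immune algorithm and (optionally) PCA+SVM on one
#' dataset and tabulates evaluation counts, overall accuracy and
#' per-class accuracy. The optimized immune algorithm's final model is
#' re-scored with the five-group rotation on its selected features and
#' parameters.
#'
#' @param data a [labeled_dataset()].
#' @param cfg an [ia_config()] for the optimized immune algorithm.
#' @param grid_size SVM baseline grid points per axis.
#' @param pca_components components for the PCA baseline (`NULL` to
#'   skip).
#' @param seed seed for the baselines' RNG use.
#' @return data.frame of class `algorithm_comparison` with one row per
#'   algorithm: `algorithm`, `evaluations`, `accuracy`,
#'   `acc_normal`, `acc_cirrhosis`, `acc_cancer`, `n_features`.
#' @export
compare_algorithms <- function(data, cfg = ia_config(), grid_size = 15L,
                               pca_components = 10L, seed = 1L) {
  set.seed(seed)
  rep_imm <- immune_classifier_baseline(data)
  rep_svm <- svm_grid_baseline(data, grid_size = grid_size,
                               c_bounds = cfg$c_bounds, r_bounds = cfg$r_bounds)
  opt <- run_optimization(data, cfg)
  ph <- opt$phenotype
  cv <- cv_accuracy(data, svm_model_spec(ph$C, ph$r),
                    columns = which(ph$mask))
  rows <- list(
    data.frame(algorithm = "immune", evaluations = rep_imm$evaluations,
               accuracy = rep_imm$overall,
               t(rep_imm$per_class), n_features = ncol(data$features)),
    data.frame(algorithm = "svm", evaluations = rep_svm$evaluations,
               accuracy = rep_svm$overall,
               t(rep_svm$per_class), n_features = ncol(data$features)),
    data.frame(algorithm = "optimized_immune",
               evaluations = opt$evaluations * 5L,
               accuracy = cv$overall, t(cv$per_class),
               n_features = sum(ph$mask)))
  if (!is.null(pca_components)) {
    rep_pca <- pca_svm_baseline(data, pca_components)
    rows <- c(rows, list(
      data.frame(algorithm = "pca_svm", evaluations = rep_pca$evaluations,
                 accuracy = rep_pca$overall, t(rep_pca$per_class),
                 n_features = pca_components)))
  }
  out <- do.call(rbind, rows)
  names(out) <- c("algorithm", "evaluations", "accuracy",
                  paste0("acc_", levels(data$labels)), "n_features")
  rownames(out) <- NULL
  attr(out, "optimization") <- opt
  class(out) <- c("algorithm_comparison", "data.frame")
  out
}
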