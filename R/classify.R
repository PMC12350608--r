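#' Classifier configuration
#'
#' Settings for the SMOTE-balanced multilayer-perceptron classifier used
#' under leave-one-out cross-validation.
#'
#' @param hidden_units_grid candidate hidden-layer sizes; with more than
#'   one value the size is tuned per training fold by inner k-fold
#'   cross-validation (mean accuracy, ties to the smaller size).
#' @param smote balance every training fold with SMOTE (default on;
#'   turning it off trains on the raw imbalanced folds).
#' @param smote_k number of same-class nearest neighbours used by SMOTE
#'   (capped at class size - 1).
#' @param center_scale standardize predictors on the training portion of
#'   each fold (subtract mean, divide by SD).
#' @param repeats number of repetitions of the whole LOOCV procedure with
#'   fresh seeds (25 is a desk-scale default; set 1000 to match
#'   full-study practice).
#' @param inner_folds folds for the inner tuning resampling.
#' @param max_epochs,decay optimiser iteration cap and weight decay for
#'   [nnet::nnet()].
#' @param seed master seed; per-repeat and per-fold seeds are derived
#'   from it deterministically.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(hidden_units_grid = c(3, 5, 8, 13, 21),
                              smote = TRUE, smote_k = 5, center_scale = TRUE,
                              repeats = 25, inner_folds = 5,
                              max_epochs = 200, decay = 5e-4,
                              seed = NULL) {
  stopifnot(all(hidden_units_grid >= 1), smote_k >= 1, repeats >= 1,
            inner_folds >= 2, max_epochs >= 1, decay >= 0)
  structure(list(hidden_units_grid = as.integer(hidden_units_grid),
                 smote = isTRUE(smote), smote_k = as.integer(smote_k),
                 center_scale = isTRUE(center_scale),
                 repeats = as.integer(repeats),
                 inner_folds = as.integer(inner_folds),
                 max_epochs = as.integer(max_epochs), decay = decay,
                 seed = seed),
            class = "classifier_config")
}

#' Standardize predictors on the training set, apply to both
#'
#' Column means and standard deviations are estimated on the training
#' matrix only and the identical transform is applied to the test matrix,
#' so no information from held-out cases leaks into preprocessing.
#' Zero-variance columns are centered but not scaled, with a warning.
#'
#' @param train numeric matrix with >= 2 rows.
#' @param test optional numeric matrix with the same columns.
#' @return List with `train`, `test` (or `NULL`), `center`, `scale`.
#' @export
standardize_fit_apply <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stop("need at least 2 training rows")
  if (any(!is.finite(train))) stop("training matrix contains non-finite values")
  ctr <- colMeans(train)
  scl <- apply(train, 2, stats::sd)
  if (any(zero <- scl == 0)) {
    warning(sprintf("%d constant column(s): centered but not scaled", sum(zero)))
    scl[zero] <- 1
  }
  tr <- sweep(sweep(train, 2, ctr), 2, scl, "/")
  te <- NULL
  if (!is.null(test)) {
    test <- matrix(as.numeric(test), ncol = ncol(train))
    if (any(!is.finite(test))) stop("test matrix contains non-finite values")
    te <- sweep(sweep(test, 2, ctr), 2, scl, "/")
  }
  list(train = tr, test = te, center = ctr, scale = scl)
}

#' SMOTE synthetic oversampling of one class
#'
#' Generates synthetic minority-class rows by interpolation between real
#' members and their same-class nearest neighbours:
#' `x_new = x_i + u * (x_nn - x_i)` with `x_nn` one of the `k` Euclidean
#' nearest neighbours of `x_i` and `u ~ U(0, 1)`.  Base points are
#' cycled so coverage of the class is even.  Synthetic points therefore
#' lie on segments between class members (inside the class's convex
#' hull).
#'
#' @param X_class numeric matrix of the class's rows (>= 2).
#' @param n_new number of synthetic rows (0 allowed).
#' @param k neighbour count, capped at `nrow(X_class) - 1`.
#' @return Numeric matrix with `n_new` rows.
#' @export
smote_oversample <- function(X_class, n_new, k = 5) {
  X <- as.matrix(X_class)
  m <- nrow(X)
  if (m < 2) stop("SMOTE needs at least 2 class members")
  if (n_new == 0) return(X[0, , drop = FALSE])
  k <- min(k, m - 1)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nn <- matrix(apply(D, 1, function(d) order(d)[seq_len(k)]),
               nrow = m, ncol = k, byrow = TRUE)
  base <- rep(seq_len(m), length.out = n_new)
  pick <- nn[cbind(base, sample.int(k, n_new, replace = TRUE))]
  u <- stats::runif(n_new)
  X[base, , drop = FALSE] + u * (X[pick, , drop = FALSE] - X[base, , drop = FALSE])
}

# Oversample every minority class up to the majority count.
smote_balance <- function(X, labels, k = 5) {
  labels <- droplevels(as.factor(labels))
  tab <- table(labels)
  target <- max(tab)
  Xs <- list(X); ls <- list(labels)
  for (g in names(tab)) {
    need <- target - tab[[g]]
    if (need == 0) next
    if (tab[[g]] < 2)
      stop(sprintf("class '%s' has a single member: SMOTE impossible", g))
    syn <- smote_oversample(X[labels == g, , drop = FALSE], need, k)
    Xs <- c(Xs, list(syn))
    ls <- c(ls, list(factor(rep(g, need), levels = levels(labels))))
  }
  list(X = do.call(rbind, Xs), labels = do.call(c, ls))
}

#' Train a single-hidden-layer perceptron
#'
#' Thin wrapper around [nnet::nnet()]: one hidden layer of logistic
#' units, softmax outputs (one per class), highest-output decision rule.
#' Training is deterministic given `seed`.
#'
#' @param X numeric predictor matrix (standardized).
#' @param labels class label per row; >= 2 classes required.
#' @param size hidden-layer size.
#' @param config a [classifier_config()] (supplies `max_epochs`,
#'   `decay`).
#' @param seed integer seed for weight initialisation.
#' @return An object of class `oto_mlp`.
#' @export
train_mlp <- function(X, labels, size, config = classifier_config(),
                      seed = NULL) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("training data contains a single class")
  fit <- with_seed(seed, nnet::nnet(
    x = as.matrix(X), y = nnet::class.ind(labels), size = size,
    softmax = TRUE, maxit = config$max_epochs, decay = config$decay,
    trace = FALSE, MaxNWts = 1e5))
  structure(list(fit = fit, levels = levels(labels), size = size),
            class = "oto_mlp")
}

#' @export
predict.oto_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  prob <- stats::predict(object$fit, as.matrix(newdata))
  if (type == "prob") return(prob)
  # ties broken toward the first class in label order
  factor(object$levels[max.col(prob, ties.method = "first")],
         levels = object$levels)
}

# Inner k-fold tuning of the hidden-layer size on the training portion.
tune_hidden_units <- function(X, labels, config, seed = NULL) {
  grid <- config$hidden_units_grid
  if (length(grid) == 1) return(grid)
  labels <- droplevels(as.factor(labels))
  n <- nrow(X)
  folds <- with_seed(seed, {
    f <- integer(n)
    for (g in levels(labels)) {
      idx <- which(labels == g)
      f[idx] <- sample(rep_len(seq_len(config$inner_folds), length(idx)))
    }
    f
  })
  acc <- sapply(seq_along(grid), function(si) {
    hits <- 0L; total <- 0L
    for (k in unique(folds)) {
      tr <- folds != k
      if (nlevels(droplevels(labels[tr])) < 2) next
      m <- train_mlp(X[tr, , drop = FALSE], labels[tr], grid[si], config,
                     seed = derive_seed(seed, si * 100 + k))
      pr <- predict(m, X[!tr, , drop = FALSE])
      hits <- hits + sum(pr == labels[!tr]); total <- total + sum(!tr)
    }
    hits / max(total, 1)
  })
  grid[which.max(acc)]  # ties resolve to the smaller (earlier) size
}

#' Leave-one-out cross-validated classification
#'
#' For each held-out observation: predictors are standardized on the
#' remaining N - 1 cases, the training portion only is SMOTE-balanced to
#' the majority class count, the hidden-layer size is tuned by inner
#' resampling on that training portion, an MLP is trained and the
#' held-out case predicted.  Predictions accumulate into a confusion
#' matrix (rows = predictions, columns = references), and the whole
#' procedure is repeated `config$repeats` times with fresh derived seeds;
#' the reported matrix is the per-repeat mean.
#'
#' SMOTE and standardization never see the held-out case, so no
#' information leaks from validation to training.
#'
#' @param X numeric predictor matrix.
#' @param labels class label per row; every class needs >= 2 members.
#' @param config a [classifier_config()].
#' @return An object of class `oto_loocv`: `cm` (mean confusion matrix),
#'   `metrics` (per-repeat accuracy and kappa), `config`,
#'   `class_labels`.
#' @export
loocv_classify <- function(X, labels, config = classifier_config()) {
  X <- as.matrix(X)
  labels <- droplevels(as.factor(labels))
  N <- nrow(X)
  K <- nlevels(labels)
  if (length(labels) != N) stop("`labels` must match rows of `X`")
  if (N < K + 1) stop("need at least one more observation than classes")
  if (any(table(labels) < 2))
    stop("every class needs >= 2 members (a class of 1 vanishes from its own training fold)")
  lev <- levels(labels)
  cms <- vector("list", config$repeats)
  met <- data.frame(repeat_ = seq_len(config$repeats), accuracy = NA_real_,
                    kappa = NA_real_)
  for (r in seq_len(config$repeats)) {
    rep_seed <- derive_seed(config$seed, r)
    pred <- factor(rep(lev[1], N), levels = lev)
    for (i in seq_len(N)) {
      fold_seed <- derive_seed(rep_seed, i)
      std <- if (config$center_scale) {
        standardize_fit_apply(X[-i, , drop = FALSE], X[i, , drop = FALSE])
      } else {
        list(train = X[-i, , drop = FALSE], test = X[i, , drop = FALSE])
      }
      bal <- if (config$smote) {
        with_seed(fold_seed, smote_balance(std$train, labels[-i], config$smote_k))
      } else list(X = std$train, labels = labels[-i])
      size <- tune_hidden_units(bal$X, bal$labels, config,
                                seed = derive_seed(fold_seed, 1))
      m <- train_mlp(bal$X, bal$labels, size, config,
                     seed = derive_seed(fold_seed, 2))
      pred[i] <- predict(m, std$test)
    }
    cm <- table(prediction = pred, reference = labels)
    cms[[r]] <- unclass(cm)
    mm <- confusion_metrics(cm)
    met$accuracy[r] <- mm$accuracy
    met$kappa[r] <- mm$kappa
  }
  cm_mean <- Reduce(`+`, cms) / length(cms)
  structure(list(cm = cm_mean, cm_repeats = cms, metrics = met,
                 config = config, class_labels = lev),
            class = "oto_loocv")
}

#' @export
print.oto_loocv <- function(x, ...) {
  cat(sprintf("<oto_loocv: %d classes, %d repeat(s)>\n",
              length(x$class_labels), nrow(x$metrics)))
  cat(sprintf("  mean accuracy %.4f, mean kappa %.4f\n",
              mean(x$metrics$accuracy), mean(x$metrics$kappa)))
  invisible(x)
}

#' Confusion-matrix metrics
#'
#' Overall accuracy, Cohen's kappa and per-class accuracy for a confusion
#' matrix with rows = predictions and columns = references:
#' `accuracy = trace / N`;
#' `kappa = (p_o - p_e) / (1 - p_e)` with expected agreement
#' `p_e = sum_i row_i * col_i / N^2` (kappa is reported as `NA` when
#' `p_e = 1`, i.e. a degenerate single-cell matrix); per-class accuracy
#' is the diagonal divided by the reference (column) total, in percent.
#'
#' @param cm square numeric matrix (or `table`), predictions in rows,
#'   references in columns, grand total > 0.
#' @return List of class `oto_confusion_metrics` with `accuracy`,
#'   `kappa`, `per_class_accuracy` (percent, named), `n`.
#' @export
confusion_metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("confusion matrix counts must be >= 0")
  N <- sum(cm)
  if (N <= 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / N
  pe <- sum(rowSums(cm) * colSums(cm)) / N^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps * 4) NA_real_ else (po - pe) / (1 - pe)
  per_class <- 100 * diag(cm) / colSums(cm)
  names(per_class) <- colnames(cm) %||% paste0("class", seq_len(ncol(cm)))
  structure(list(accuracy = po, kappa = kappa,
                 per_class_accuracy = per_class, n = N),
            class = "oto_confusion_metrics")
}

#' @export
print.oto_confusion_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f, kappa %s, n = %d\n", x$accuracy,
              ifelse(is.na(x$kappa), "NA (degenerate)", sprintf("%.4f", x$kappa)),
              round(x$n)))
  cat("per-class accuracy (%):\n")
  print(round(x$per_class_accuracy, 2))
  invisible(x)
}

#' Permutation importance of input components
#'
#' Ranks input components by how much shuffling each one degrades the
#' accuracy of a small ensemble of MLPs trained on the full standardized
#' data: importance is the mean accuracy drop over `n_shuffles`
#' label-preserving column permutations, averaged over `n_models`
#' independently initialised models.
#'
#' @param X numeric predictor matrix.
#' @param labels class labels.
#' @param config a [classifier_config()] (first grid entry is used as the
#'   hidden size).
#' @param n_models ensemble size.
#' @param n_shuffles shuffles per column.
#' @param seed integer seed.
#' @return Data frame (`component`, `importance`) sorted by decreasing
#'   importance.
#' @export
pc_importance <- function(X, labels, config = classifier_config(),
                          n_models = 5, n_shuffles = 10, seed = NULL) {
  X <- as.matrix(X)
  labels <- droplevels(as.factor(labels))
  std <- standardize_fit_apply(X)
  Z <- std$train
  size <- config$hidden_units_grid[1]
  models <- lapply(seq_len(n_models), function(m)
    train_mlp(Z, labels, size, config, seed = derive_seed(seed, m)))
  acc <- function(M, W) mean(predict(M, W) == labels)
  base <- vapply(models, acc, numeric(1), W = Z)
  drops <- with_seed(derive_seed(seed, 999), {
    sapply(seq_len(ncol(Z)), function(j) {
      mean(vapply(seq_len(n_shuffles), function(s) {
        W <- Z
        W[, j] <- W[sample.int(nrow(W)), j]
        mean(base - vapply(models, acc, numeric(1), W = W))
      }, numeric(1)))
    })
  })
  out <- data.frame(component = colnames(X) %||% paste0("PC", seq_len(ncol(X))),
                    importance = drops)
  out[order(-out$importance), , drop = FALSE]
}

#' Correlation of component scores with wavelet positions
#'
#' For each selected component, the Pearson correlation between its score
#' and each of the 512 wavelet-coefficient positions, localising which
#' part of the outline the component describes.
#'
#' @param scores component score matrix.
#' @param features wavelet feature matrix (same rows).
#' @param components columns of `scores` to correlate (default first 4).
#' @return Matrix, positions x selected components.
#' @export
pc_wavelet_correlation <- function(scores, features,
                                   components = seq_len(min(4, ncol(scores)))) {
  scores <- as.matrix(scores); features <- as.matrix(features)
  if (nrow(scores) != nrow(features)) stop("row mismatch")
  out <- stats::cor(features, scores[, components, drop = FALSE])
  colnames(out) <- (colnames(scores) %||% paste0("PC", seq_len(ncol(scores))))[components]
  out
}
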