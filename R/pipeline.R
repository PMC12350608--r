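#' Control parameters for the full analysis
#'
#' Collects every stage's tunable parameters.  Defaults follow standard
#' practice for wavelet-based otolith outline analysis: 512 signature
#' points, nine wavelet scales with the fourth as the feature scale,
#' broken-stick component retention, PERMANOVA with 9,999 permutations,
#' and five morphotypes.
#'
#' @param n_points signature length (power of two; 512).
#' @param levels wavelet decomposition depth (9 for 512 points).
#' @param wavelet_scale detail scale used as the feature vector (4).
#' @param adjust size-correct `"all"` retained components or only those
#'   with a `"significant"` size correlation at `alpha`.
#' @param alpha screening level for `adjust = "significant"`.
#' @param min_retained abort if broken-stick retains fewer components
#'   than this (downstream stages need a multivariate space).
#' @param n_perm PERMANOVA permutations.
#' @param pairwise also run pairwise PERMANOVA.
#' @param classifier a [classifier_config()].
#' @param k_morphotypes number of morphotypes cut from the Ward tree.
#' @param silhouette_range candidate k values profiled to support the
#'   choice of `k_morphotypes`.
#' @param morphotype_test run the (circular) PERMANOVA among morphotypes.
#' @param assume_left treat contours with unknown side as left otoliths.
#' @return A list of class `otoshape_control`.
#' @export
otoshape_control <- function(n_points = 512, levels = 9, wavelet_scale = 4,
                             adjust = c("all", "significant"), alpha = 0.05,
                             min_retained = 2,
                             n_perm = 9999, pairwise = TRUE,
                             classifier = classifier_config(),
                             k_morphotypes = 5, silhouette_range = 2:10,
                             morphotype_test = FALSE,
                             assume_left = TRUE) {
  adjust <- match.arg(adjust)
  stopifnot(n_points >= 8, 2^levels <= n_points,
            wavelet_scale >= 1, wavelet_scale <= levels,
            n_perm >= 1, k_morphotypes >= 1)
  structure(list(n_points = as.integer(n_points), levels = as.integer(levels),
                 wavelet_scale = as.integer(wavelet_scale), adjust = adjust,
                 alpha = alpha, min_retained = as.integer(min_retained),
                 n_perm = as.integer(n_perm), pairwise = isTRUE(pairwise),
                 classifier = classifier,
                 k_morphotypes = as.integer(k_morphotypes),
                 silhouette_range = silhouette_range,
                 morphotype_test = isTRUE(morphotype_test),
                 assume_left = isTRUE(assume_left)),
            class = "otoshape_control")
}

#' Fit the full otolith shape analysis
#'
#' Runs the complete pipeline on a dataset of otolith outlines:
#' \enumerate{
#'   \item orient each contour (left-otolith convention), resample to
#'     `n_points` equidistant vertices and compute the normalised
#'     centroid-distance signature;
#'   \item decompose each signature with the a trous B3-spline transform
#'     and keep detail scale `wavelet_scale` as the feature vector;
#'   \item covariance PCA of the features, broken-stick retention,
#'     Pearson size screening and allometric residualisation of the
#'     retained scores against otolith length;
#'   \item PERMANOVA (Manhattan distance) among populations, global and
#'     pairwise with Bonferroni correction;
#'   \item SMOTE-balanced MLP classification under leave-one-out
#'     cross-validation;
#'   \item Ward clustering into morphotypes with composition summaries
#'     and a silhouette profile.
#' }
#'
#' @param data an `oto_dataset` (see [generate_metapopulation()]), an
#'   `oto_manifest` from [read_manifest()], or a manifest file path.
#' @param config an [otoshape_control()].
#' @param seed master seed; all stage seeds are derived from it.
#' @return An object of class `otoshape`; see [summary.otoshape()].
#' @export
otoshape <- function(data, config = otoshape_control(), seed = 1L) {
  if (is.character(data)) data <- read_manifest(data)
  if (inherits(data, "oto_manifest")) data <- load_manifest_dataset(data)
  stopifnot(inherits(data, "oto_dataset"))
  n <- length(data$contours)
  labels <- as.factor(data$labels)

  contours <- lapply(data$contours, function(ct)
    resample_equidistant(canonical_orientation(ct, assume_left = config$assume_left),
                         config$n_points))
  sig <- lapply(contours, shape_signature)
  signatures <- do.call(rbind, lapply(sig, `[[`, "distances"))
  sizes <- data$sizes
  if (is.null(sizes) || any(is.na(sizes)))
    sizes <- vapply(contours, otolith_length, numeric(1))

  features <- do.call(rbind, lapply(seq_len(n), function(i)
    as.numeric(select_scale(atrous_decompose(signatures[i, ], config$levels),
                            config$wavelet_scale))))
  rownames(features) <- rownames(signatures) <- NULL

  pca <- pca_covariance(features)
  retained <- broken_stick_retain(pca$eigenvalues)
  if (retained < config$min_retained)
    stop(sprintf(paste(
      "broken-stick retains only %d component(s); the downstream stages need",
      "at least %d.  The data may be too uniform: check the feature scale,",
      "or lower `min_retained` deliberately."), retained, config$min_retained))
  scores <- pca$scores[, seq_len(retained), drop = FALSE]
  sizecor <- size_correlation(scores, sizes)
  comps <- if (config$adjust == "significant") which(sizecor$p < config$alpha) else NULL
  adj <- allometric_residuals(scores, sizes, labels, components = comps)

  D <- manhattan_distances(adj$scores)
  perm_global <- permanova_global(D, labels, n_perm = config$n_perm,
                                  seed = derive_seed(seed, 41))
  perm_pairwise <- if (config$pairwise && nlevels(labels) > 2)
    permanova_pairwise(D, labels, n_perm = config$n_perm,
                       seed = derive_seed(seed, 42)) else NULL

  cls_cfg <- config$classifier
  cls_cfg$seed <- cls_cfg$seed %||% derive_seed(seed, 43)
  loocv <- loocv_classify(adj$scores, labels, cls_cfg)

  dendro <- ward_cluster(adj$scores)
  morphotype <- cut_tree(dendro, config$k_morphotypes)
  composition <- morphotype_composition(morphotype, labels)
  silhouettes <- silhouette_profile(adj$scores, config$silhouette_range)
  mt_test <- if (config$morphotype_test)
    suppressWarnings(morphotype_separation_test(adj$scores, morphotype,
                                                n_perm = config$n_perm,
                                                seed = derive_seed(seed, 44))) else NULL

  # final classifier on all data, for predicting new otoliths
  std <- standardize_fit_apply(adj$scores)
  bal <- with_seed(derive_seed(seed, 45),
                   smote_balance(std$train, labels, cls_cfg$smote_k))
  fin_size <- tune_hidden_units(bal$X, bal$labels, cls_cfg,
                                seed = derive_seed(seed, 46))
  final_model <- train_mlp(bal$X, bal$labels, fin_size, cls_cfg,
                           seed = derive_seed(seed, 47))

  structure(list(signatures = signatures, features = features,
                 sizes = sizes, labels = labels,
                 pca = pca, retained = retained, size_correlation = sizecor,
                 size_adjusted = adj,
                 permanova = perm_global, permanova_pairwise = perm_pairwise,
                 loocv = loocv,
                 dendrogram = dendro, morphotype = morphotype,
                 composition = composition, silhouettes = silhouettes,
                 morphotype_test = mt_test,
                 final_model = final_model, final_standardize = std,
                 config = config, seed = seed, call = match.call()),
            class = "otoshape")
}

#' @export
print.otoshape <- function(x, ...) {
  cat(sprintf("otoshape fit: %d otoliths, %d populations\n",
              nrow(x$features), nlevels(x$labels)))
  cat(sprintf("  retained components (broken stick): %d (%.1f%% of variance)\n",
              x$retained, 100 * sum(x$pca$variance_fraction[seq_len(x$retained)])))
  cat(sprintf("  PERMANOVA: pseudo-F = %.3f, p = %.4g\n",
              x$permanova$pseudo_F, x$permanova$p_value))
  cat(sprintf("  LOOCV: mean accuracy %.3f, mean kappa %.3f\n",
              mean(x$loocv$metrics$accuracy), mean(x$loocv$metrics$kappa)))
  cat(sprintf("  morphotypes: k = %d\n", x$config$k_morphotypes))
  invisible(x)
}

#' Summarise a fitted otolith shape analysis
#'
#' @param object an `otoshape` fit.
#' @param ... unused.
#' @return The object, invisibly, after printing eigenvalue fractions,
#'   size correlations, PERMANOVA, classification metrics and morphotype
#'   composition.
#' @export
summary.otoshape <- function(object, ...) {
  print(object)
  cat("\nVariance fractions of retained components:\n")
  print(round(object$pca$variance_fraction[seq_len(object$retained)], 4))
  cat("\nSize correlations (retained components):\n")
  sc <- object$size_correlation
  sc$r <- round(sc$r, 3); sc$p <- signif(sc$p, 3)
  print(sc)
  cat("\nConfusion matrix (mean over repeats; rows = predictions):\n")
  print(round(object$loocv$cm, 1))
  cm <- confusion_metrics(object$loocv$cm)
  cat("\n"); print(cm)
  cat("\nMorphotype composition:\n")
  print(object$composition)
  invisible(object)
}

#' Plot a fitted otolith shape analysis
#'
#' Two-panel display: the size-adjusted morphospace (first two retained
#' components, coloured by population) and the per-population mean
#' wavelet feature curves along the 512 outline positions.
#'
#' @param x an `otoshape` fit.
#' @param which `"morphospace"`, `"wavelet"` or both.
#' @param ... unused.
#' @export
plot.otoshape <- function(x, which = c("morphospace", "wavelet"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  lev <- levels(x$labels)
  cols <- grDevices::hcl.colors(max(3, length(lev)), "Dark 3")[seq_along(lev)]
  if (length(which) == 2) {
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  }
  if ("morphospace" %in% which) {
    s <- x$size_adjusted$scores
    graphics::plot(s[, 1], s[, 2], col = cols[as.integer(x$labels)], pch = 19,
                   cex = 0.6, xlab = "PC1 (size-adjusted)",
                   ylab = "PC2 (size-adjusted)", main = "Morphospace")
    graphics::legend("topright", legend = lev, col = cols, pch = 19, cex = 0.6)
  }
  if ("wavelet" %in% which) {
    md <- mean_contour_decomposition(x$features, x$labels)
    graphics::plot(NULL, xlim = c(1, ncol(x$features)),
                   ylim = range(md$mean), xlab = "outline position",
                   ylab = sprintf("scale-%d detail", x$config$wavelet_scale),
                   main = "Mean contour decomposition")
    for (i in seq_along(lev)) graphics::lines(md$mean[i, ], col = cols[i])
    graphics::lines(md$grand_mean, lty = 2)
  }
  invisible(x)
}

#' Classify new otoliths with a fitted analysis
#'
#' Projects new contours through the fitted pipeline (orientation,
#' signature, wavelet features, PCA projection, allometric adjustment
#' with the stored common slopes, standardization) and predicts their
#' population with the final MLP trained on all fitted data.
#'
#' @param object an `otoshape` fit.
#' @param newdata an `oto_dataset`, or a list of [oto_contour].
#' @param sizes otolith lengths (mm) for the new contours; measured from
#'   the contours when omitted.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return Factor of predicted populations (or a probability matrix).
#' @export
predict.otoshape <- function(object, newdata, sizes = NULL,
                             type = c("class", "prob"), ...) {
  type <- match.arg(type)
  contours <- if (inherits(newdata, "oto_dataset")) newdata$contours else newdata
  if (inherits(contours, "oto_contour")) contours <- list(contours)
  if (is.null(sizes) && inherits(newdata, "oto_dataset")) sizes <- newdata$sizes
  cfg <- object$config
  contours <- lapply(contours, function(ct)
    resample_equidistant(canonical_orientation(ct, assume_left = cfg$assume_left),
                         cfg$n_points))
  if (is.null(sizes)) sizes <- vapply(contours, otolith_length, numeric(1))
  sigs <- do.call(rbind, lapply(contours, function(ct) shape_signature(ct)$distances))
  feats <- do.call(rbind, lapply(seq_len(nrow(sigs)), function(i)
    as.numeric(select_scale(atrous_decompose(sigs[i, ], cfg$levels),
                            cfg$wavelet_scale))))
  sc <- sweep(feats, 2, object$pca$center) %*%
    object$pca$loadings[, seq_len(object$retained), drop = FALSE]
  adjv <- object$size_adjusted
  for (j in which(adjv$adjusted))
    sc[, j] <- sc[, j] - adjv$slopes[j] * (sizes - adjv$grand_mean_size)
  z <- sweep(sweep(sc, 2, object$final_standardize$center), 2,
             object$final_standardize$scale, "/")
  predict(object$final_model, z, type = type)
}

#' Reference 11-river LOOCV confusion matrix
#'
#' The published leave-one-out confusion matrix for 1,141 American shad
#' from 11 rivers (rows = predicted river, columns = reference river),
#' shipped as a plain-text worked example for [confusion_metrics()].
#'
#' @return Integer matrix 11 x 11 with river-code dimnames.
#' @export
shad_confusion_matrix <- function() {
  path <- system.file("extdata", "shad_loocv_confusion.csv",
                      package = "otoshape", mustWork = TRUE)
  as.matrix(read_matrix_csv(path))
}
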