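#' Covariance-matrix principal component analysis
#'
#' PCA on the column variance-covariance matrix of the feature matrix:
#' columns are mean-centered but not variance-scaled, since the wavelet
#' coefficients share a common (dimensionless) scale and their relative
#' amplitude carries shape information.  Component signs follow a
#' deterministic convention: in each loading vector the element of largest
#' magnitude is positive.
#'
#' @param features numeric matrix, individuals x variables, no missing
#'   values, at least 3 rows.
#' @return An object of class `oto_pca`: `eigenvalues` (component
#'   variances, non-increasing), `loadings` (orthonormal columns),
#'   `scores` (centered data projected on the loadings),
#'   `variance_fraction`, `center` and `totvar`.
#' @export
pca_covariance <- function(features) {
  X <- as.matrix(features)
  if (nrow(X) < 3) stop("PCA needs at least 3 observations")
  if (any(!is.finite(X))) stop("feature matrix contains missing or non-finite values")
  totvar <- sum(apply(X, 2, stats::var))
  if (totvar <= 0) stop("feature matrix is constant: zero covariance")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- seq_along(ev)
  load <- pc$rotation[, keep, drop = FALSE]
  scores <- pc$x[, keep, drop = FALSE]
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]) < 0)
  load[, flip] <- -load[, flip]
  scores[, flip] <- -scores[, flip]
  structure(list(eigenvalues = ev, loadings = load, scores = scores,
                 variance_fraction = ev / sum(ev), center = pc$center,
                 totvar = totvar),
            class = "oto_pca")
}

#' @export
print.oto_pca <- function(x, ...) {
  k <- min(5, length(x$eigenvalues))
  cat(sprintf("<oto_pca: %d obs x %d vars, %d components>\n",
              nrow(x$scores), length(x$center), length(x$eigenvalues)))
  cat("  leading variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction[seq_len(k)]), collapse = " "), "\n")
  invisible(x)
}

#' Broken-stick component retention
#'
#' Compares observed eigenvalue fractions with the broken-stick null
#' expectation `b_i = (1/p) * sum_{j=i..p} 1/j` and retains the leading
#' consecutive run of components whose observed fraction exceeds the
#' expectation (stopping at the first failure).  With `rule = "any"` all
#' components above expectation are counted instead.
#'
#' @param eigenvalues non-negative eigenvalues (any common scaling).
#' @param rule `"run"` (default) or `"any"`.
#' @return Integer count of retained components (possibly 0), with the
#'   expected fractions in attribute `"expected"`.
#' @export
broken_stick_retain <- function(eigenvalues, rule = c("run", "any")) {
  rule <- match.arg(rule)
  ev <- as.numeric(eigenvalues)
  if (length(ev) < 1 || any(ev < 0)) stop("eigenvalues must be non-negative")
  tot <- sum(ev)
  if (tot <= 0) stop("all eigenvalues are zero")
  p <- length(ev)
  frac <- ev / tot
  expected <- rev(cumsum(1 / rev(seq_len(p)))) / p
  above <- frac > expected
  k <- if (rule == "run") {
    if (!above[1]) 0L else (which(c(!above, TRUE))[1] - 1L)
  } else sum(above)
  structure(as.integer(k), expected = expected)
}

#' Pearson correlation of component scores with otolith size
#'
#' Screens each component for an allometric size effect: product-moment
#' correlation of the score with otolith length and a two-sided p value
#' from the t transform with n - 2 degrees of freedom.  No
#' multiple-testing correction is applied to this screen; treat the p
#' values as descriptive.
#'
#' @param scores numeric matrix (or vector) of component scores.
#' @param sizes otolith lengths, same length as rows of `scores`.
#' @return Data frame with `component`, `r`, `p`.
#' @export
size_correlation <- function(scores, sizes) {
  S <- as.matrix(scores)
  n <- nrow(S)
  if (n < 3) stop("need at least 3 observations")
  if (length(sizes) != n) stop("`sizes` must match rows of `scores`")
  if (stats::var(sizes) <= 0) stop("sizes do not vary")
  r <- as.numeric(stats::cor(S, sizes))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  data.frame(component = colnames(S) %||% paste0("PC", seq_len(ncol(S))),
             r = r, p = p, row.names = NULL)
}

#' Allometric size correction by common within-group slopes
#'
#' Removes the shared size trend from each component while preserving
#' between-group differences.  Per component the pooled within-group
#' slope is `b = sum_g Sxy(g) / sum_g Sxx(g)` and the adjusted score is
#' `y' = y - b * (x - grand mean of x)`.  Because a common offset of `x`
#' is used (not group means), group mean differences in `y` are carried
#' through intact — full per-group ANCOVA residuals would also strip the
#' group signal that downstream classification needs.
#'
#' @param scores numeric matrix of component scores.
#' @param sizes otolith lengths (mm).
#' @param groups population label per row; every group needs >= 2
#'   members and sizes must vary within at least one group.
#' @param components columns to adjust (default all).
#' @return An object of class `oto_sizeadj`: `scores` (adjusted matrix),
#'   `slopes` (pooled within-group slope per component), `groups`,
#'   `grand_mean_size`, `adjusted` (logical per column).
#' @export
allometric_residuals <- function(scores, sizes, groups, components = NULL) {
  S <- as.matrix(scores)
  groups <- as.factor(groups)
  n <- nrow(S)
  if (length(sizes) != n || length(groups) != n)
    stop("`sizes` and `groups` must match rows of `scores`")
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  if (is.null(components)) components <- seq_len(ncol(S))
  x <- sizes
  gx <- stats::ave(x, groups)      # group means of size
  dx <- x - gx
  sxx <- sum(dx^2)                 # pooled within-group Sxx
  if (sxx <= 0) stop("no within-group size variation: slope undefined")
  xbar <- mean(x)
  slopes <- rep(NA_real_, ncol(S))
  adjusted <- rep(FALSE, ncol(S))
  out <- S
  for (j in components) {
    y <- S[, j]
    b <- sum(dx * (y - stats::ave(y, groups))) / sxx
    out[, j] <- y - b * (x - xbar)
    slopes[j] <- b
    adjusted[j] <- TRUE
  }
  names(slopes) <- colnames(S) %||% paste0("PC", seq_len(ncol(S)))
  structure(list(scores = out, slopes = slopes, groups = groups,
                 grand_mean_size = xbar, adjusted = adjusted),
            class = "oto_sizeadj")
}

#' @export
print.oto_sizeadj <- function(x, ...) {
  cat(sprintf("<oto_sizeadj: %d obs, %d/%d components size-adjusted>\n",
              nrow(x$scores), sum(x$adjusted), ncol(x$scores)))
  invisible(x)
}
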