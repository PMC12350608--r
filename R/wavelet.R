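#' Undecimated a trous wavelet decomposition of a shape signature
#'
#' Decomposes a periodic signal of dyadic length with the stationary
#' ("a trous", with holes) wavelet transform paired with the B3-spline
#' smoothing kernel `(1, 4, 6, 4, 1) / 16`.  Starting from `c_0 = x`,
#' each scale `j` smooths with the kernel dilated by inserting
#' `2^(j-1) - 1` zeros between taps (circular convolution, periodic
#' boundary — the natural extension for a closed-curve signature) and
#' takes the detail as the smoothing difference:
#' `c_j = c_{j-1} * h_j`, `d_j = c_{j-1} - c_j`.
#' The transform is undecimated, so every series keeps the input length,
#' and is exactly additive: `x = smooth + sum_j d_j`.
#'
#' A 512-point signature yields nine detail scales (`2^9 = 512`); the
#' fourth is the conventional feature scale for population discrimination.
#'
#' @param x numeric signal of length `2^levels` or more (a power of two),
#'   or an `oto_signature`.
#' @param levels number of detail scales (default 9).
#' @return An object of class `oto_swt`: list with `details` (matrix,
#'   one column per scale `d1..d<levels>`), `smooth` (final
#'   approximation), `kernel`, `boundary = "periodic"` and `input`.
#' @export
atrous_decompose <- function(x, levels = 9) {
  if (inherits(x, "oto_signature")) x <- x$distances
  x <- as.numeric(x)
  n <- length(x)
  if (any(!is.finite(x))) stop("input signal must be finite")
  if (levels < 1) stop("`levels` must be >= 1")
  if (2^levels > n) stop(sprintf("levels = %d needs a signal of length >= %d", levels, 2^levels))
  h <- c(1, 4, 6, 4, 1) / 16
  details <- matrix(0, n, levels, dimnames = list(NULL, paste0("d", seq_len(levels))))
  c_prev <- x
  for (j in seq_len(levels)) {
    step <- 2^(j - 1)
    c_new <- numeric(n)
    for (k in -2:2) c_new <- c_new + h[k + 3] * circ_shift(c_prev, k * step)
    details[, j] <- c_prev - c_new
    c_prev <- c_new
  }
  structure(list(details = details, smooth = c_prev, kernel = h,
                 boundary = "periodic", input = x),
            class = "oto_swt")
}

#' @export
print.oto_swt <- function(x, ...) {
  cat(sprintf("<oto_swt: %d samples, %d detail scales, B3-spline kernel, periodic>\n",
              length(x$input), ncol(x$details)))
  invisible(x)
}

#' Extract one detail scale as the per-otolith feature vector
#'
#' @param decomp an `oto_swt` from [atrous_decompose()].
#' @param scale detail scale to extract (default 4, the scale that best
#'   separates populations in otolith contour studies).
#' @return Numeric vector (the selected detail series) with attributes
#'   `scale`.
#' @export
select_scale <- function(decomp, scale = 4) {
  stopifnot(inherits(decomp, "oto_swt"))
  if (scale < 1 || scale > ncol(decomp$details))
    stop(sprintf("`scale` must be between 1 and %d", ncol(decomp$details)))
  structure(decomp$details[, scale], scale = scale)
}

#' Per-group mean and spread of wavelet feature curves
#'
#' Summarises a feature matrix (individuals x positions) into pointwise
#' per-group mean and standard-deviation curves plus the grand-mean curve,
#' the standard display for comparing population-average contour
#' decompositions.
#'
#' @param features numeric matrix, one row per individual.
#' @param groups group label per row.
#' @param sd_type `"sample"` (n - 1 denominator, default) or
#'   `"population"` (n); single-member groups get SD 0.
#' @return List with `mean` (groups x positions), `sd`, `grand_mean` and
#'   `sd_type`.
#' @export
mean_contour_decomposition <- function(features, groups, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  features <- as.matrix(features)
  groups <- as.factor(groups)
  if (nrow(features) != length(groups)) stop("`groups` must match rows of `features`")
  if (any(table(groups) == 0)) stop("empty group level")
  gm <- colMeans(features)
  means <- t(sapply(levels(groups), function(g) colMeans(features[groups == g, , drop = FALSE])))
  sds <- t(sapply(levels(groups), function(g) {
    sub <- features[groups == g, , drop = FALSE]
    if (nrow(sub) == 1) return(rep(0, ncol(sub)))
    s <- apply(sub, 2, stats::sd)
    if (sd_type == "population") s <- s * sqrt((nrow(sub) - 1) / nrow(sub))
    s
  }))
  list(mean = means, sd = sds, grand_mean = gm, sd_type = sd_type)
}
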