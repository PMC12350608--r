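#' Construct an otolith contour object
#'
#' A contour is an ordered closed polygon describing an otolith outline.
#' The first vertex is not repeated at the end; closure is implicit.
#'
#' @param vertices two-column numeric matrix (x, y), one vertex per row,
#'   at least 3 rows, first row different from the last.
#' @param side which otolith the outline comes from, `"left"` or `"right"`
#'   (or `NA` if unknown).  All analyses use the left-otolith convention;
#'   right otoliths are mirrored by [canonical_orientation()].
#' @param units coordinate units, `"mm"` or `"px"`.
#' @param scale for pixel-unit contours, the physical size of one pixel in
#'   mm (`NA` if unknown).
#' @return An object of class `oto_contour`.
#' @export
oto_contour <- function(vertices, side = "left", units = "mm", scale = NA_real_) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2)
    stop("`vertices` must be a numeric matrix with two columns (x, y)")
  if (nrow(vertices) < 3) stop("a contour needs at least 3 vertices")
  if (any(!is.finite(vertices))) stop("contour vertices must be finite")
  n <- nrow(vertices)
  if (all(vertices[1, ] == vertices[n, ])) vertices <- vertices[-n, , drop = FALSE]
  if (nrow(vertices) < 3) stop("a contour needs at least 3 distinct vertices")
  if (!side %in% c("left", "right") && !is.na(side))
    stop("`side` must be \"left\", \"right\" or NA")
  if (!units %in% c("mm", "px")) stop("`units` must be \"mm\" or \"px\"")
  dimnames(vertices) <- list(NULL, c("x", "y"))
  structure(list(vertices = vertices, closed = TRUE, side = side,
                 units = units, scale = scale),
            class = "oto_contour")
}

#' @export
print.oto_contour <- function(x, ...) {
  cat(sprintf("<oto_contour: %d vertices, side = %s, units = %s>\n",
              nrow(x$vertices), x$side, x$units))
  invisible(x)
}

as_contour <- function(x) {
  if (inherits(x, "oto_contour")) return(x)
  oto_contour(x)
}

# Signed area via the shoelace formula; > 0 for counterclockwise traversal.
signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- circ_shift(x, 1); yn <- circ_shift(y, 1)
  sum(x * yn - xn * y) / 2
}

ensure_ccw <- function(contour) {
  if (signed_area(contour$vertices) < 0)
    contour$vertices <- contour$vertices[rev(seq_len(nrow(contour$vertices))), , drop = FALSE]
  contour
}

#' Area centroid of a closed polygon
#'
#' Computes the area (mass) centroid of a simple closed polygon using the
#' shoelace moment formulas.  This is the reference point from which the
#' shape signature measures centroid distances; unlike the plain vertex
#' average it is insensitive to uneven vertex density along the outline.
#'
#' @param contour an [oto_contour] (or a two-column vertex matrix).
#' @return Numeric length-2 vector `c(x, y)`.
#' @export
polygon_centroid <- function(contour) {
  xy <- as_contour(contour)$vertices
  x <- xy[, 1]; y <- xy[, 2]
  xn <- circ_shift(x, 1); yn <- circ_shift(y, 1)
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12 * max(1, max(abs(xy))^2))
    stop("degenerate polygon: area is (numerically) zero")
  c(x = sum((x + xn) * cr) / (6 * a), y = sum((y + yn) * cr) / (6 * a))
}

#' Mirror right otoliths into the left-otolith convention
#'
#' Otoliths are conventionally imaged with the sulcus acusticus facing up
#' and the rostrum pointing right.  So that left and right otoliths of the
#' same shape yield the same signature, right otoliths are reflected about
#' the vertical axis and re-ordered counterclockwise.
#'
#' @param contour an [oto_contour] with known `side`.
#' @param assume_left if `TRUE`, contours with unknown side are treated as
#'   left otoliths instead of raising an error.
#' @return The contour in left-otolith orientation, counterclockwise.
#' @export
canonical_orientation <- function(contour, assume_left = FALSE) {
  contour <- as_contour(contour)
  side <- contour$side
  if (is.na(side)) {
    if (!assume_left) stop("otolith side is unknown; pass assume_left = TRUE to proceed")
    side <- "left"
  }
  if (side == "right") {
    contour$vertices[, 1] <- -contour$vertices[, 1]
    contour$side <- "left"
  }
  ensure_ccw(contour)
}

#' Resample a closed contour at equal arc-length spacing
#'
#' Places exactly `n` points along the polygon perimeter at spacing
#' `perimeter / n`, interpolating linearly between source vertices, in
#' counterclockwise traversal.  With the default `anchor = "farthest"`
#' the first output point is the source vertex farthest from the area
#' centroid, which makes the downstream signature independent of which
#' vertex the input polygon happens to start at; `anchor = "first"`
#' starts at the first input vertex.
#'
#' @param contour an [oto_contour].
#' @param n number of output points (default 512, the signature length).
#' @param anchor where the first resampled point sits (see above).
#' @return An [oto_contour] with exactly `n` vertices.
#' @export
resample_equidistant <- function(contour, n = 512,
                                 anchor = c("farthest", "first")) {
  anchor <- match.arg(anchor)
  contour <- ensure_ccw(as_contour(contour))
  if (n < 3) stop("`n` must be at least 3")
  xy <- contour$vertices
  if (anchor == "farthest") {
    ctr <- polygon_centroid(contour)
    i0 <- which.max((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
    if (i0 > 1) xy <- xy[c(i0:nrow(xy), 1:(i0 - 1)), , drop = FALSE]
  }
  closed <- rbind(xy, xy[1, ])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L <= 0) stop("degenerate polygon: zero perimeter")
  target <- (seq_len(n) - 1) * L / n
  newx <- stats::approx(s, closed[, 1], xout = target, ties = "ordered")$y
  newy <- stats::approx(s, closed[, 2], xout = target, ties = "ordered")$y
  out <- contour
  out$vertices <- cbind(x = newx, y = newy)
  out
}

#' Centroid-distance shape signature
#'
#' Converts a (resampled) closed contour into the one-dimensional shape
#' signature used by the wavelet stage: distances from the polygon area
#' centroid to each vertex, divided by their mean (so the signature has
#' mean 1 and is invariant to uniform scaling), and circularly rotated so
#' that index 1 is the farthest point from the centroid.  Exact ties for
#' the farthest point are broken toward the smallest index in
#' counterclockwise order, with a warning.
#'
#' @param contour an [oto_contour], normally already resampled to 512
#'   equidistant points with [resample_equidistant()].
#' @return An object of class `oto_signature` with elements `distances`
#'   (normalised), `centroid`, `mean_radius`, `start_index` (index of the
#'   farthest point in the input vertex order) and `orientation`.
#' @export
shape_signature <- function(contour) {
  contour <- ensure_ccw(as_contour(contour))
  ctr <- polygon_centroid(contour)
  xy <- contour$vertices
  d <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
  if (any(d <= 0)) stop("contour passes through its centroid; signature undefined")
  mr <- mean(d)
  dn <- d / mr
  mx <- max(dn)
  ties <- which(dn >= mx * (1 - 1e-12))
  if (length(ties) > 1)
    warning(sprintf("%d exactly tied farthest points; using the smallest index (%d)",
                    length(ties), ties[1]))
  i0 <- ties[1]
  structure(list(distances = circ_shift(dn, i0 - 1),
                 centroid = ctr, mean_radius = mr,
                 start_index = i0, orientation = "ccw"),
            class = "oto_signature")
}

#' @export
print.oto_signature <- function(x, ...) {
  cat(sprintf("<oto_signature: %d points, mean radius %.4g, start index %d>\n",
              length(x$distances), x$mean_radius, x$start_index))
  invisible(x)
}

#' Otolith length from a contour
#'
#' The otolith length (OL) is the maximum extent along the anteroposterior
#' (x) axis after canonical orientation, in mm.
#'
#' @param contour an [oto_contour] in mm units, or in px units with a
#'   known mm-per-pixel `scale`.
#' @return Length in mm.
#' @export
otolith_length <- function(contour) {
  contour <- as_contour(contour)
  f <- 1
  if (contour$units == "px") {
    if (is.na(contour$scale))
      stop("contour is in pixel units with unknown scale; cannot report mm")
    f <- contour$scale
  }
  f * diff(range(contour$vertices[, 1]))
}

#' Extract the outline of a binary silhouette
#'
#' Traces the boundary of the largest connected foreground region of a
#' binary mask at sub-pixel precision (marching squares at level 0.5 on
#' pixel-center coordinates).  Interior holes and smaller components are
#' ignored; if two components tie in enclosed area the first found is used
#' with a warning.
#'
#' @param mask an `oto_mask` from [render_binary_image()], or a numeric
#'   matrix of 0/1 values with `mask[i, j]` the pixel in column `i` (x)
#'   and row `j` (y), pixel centers at integer coordinates.
#' @return An [oto_contour], counterclockwise, in the mask's units.
#' @export
extract_contour <- function(mask) {
  if (inherits(mask, "oto_mask")) {
    m <- mask$values; xs <- mask$x; ys <- mask$y
    units <- mask$units; scale <- mask$scale; side <- mask$side
  } else {
    m <- as.matrix(mask)
    xs <- seq_len(nrow(m)); ys <- seq_len(ncol(m))
    units <- "px"; scale <- NA_real_; side <- NA_character_
  }
  if (!any(m > 0.5)) stop("empty mask: no foreground pixels")
  cl <- grDevices::contourLines(xs, ys, m, levels = 0.5)
  if (length(cl) == 0) stop("no closed boundary found (foreground touches the mask edge?)")
  areas <- vapply(cl, function(p) abs(signed_area(cbind(p$x, p$y))), numeric(1))
  best <- which.max(areas)
  if (length(areas) > 1) {
    second <- max(areas[-best])
    if (second >= areas[best] * (1 - 1e-9))
      warning("two boundary components of equal size; keeping the first found")
  }
  xy <- cbind(cl[[best]]$x, cl[[best]]$y)
  if (all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  ensure_ccw(oto_contour(xy, side = side, units = units, scale = scale))
}
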