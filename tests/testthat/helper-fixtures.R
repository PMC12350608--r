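# Geometric fixtures and independent oracles shared across tests.

circle_contour <- function(n = 2048, r = 1, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  oto_contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th)))
}

ellipse_contour <- function(a = 2, b = 1, n = 4096, phase = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)] + phase
  oto_contour(cbind(a * cos(th), b * sin(th)))
}

# Random star-shaped polygon: simple by construction (positive radius at
# strictly increasing angles).
star_polygon <- function(seed, n = 256) {
  set.seed(seed)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- 1 + 0.3 * sin(3 * th + runif(1, 0, 2 * pi)) + rnorm(n, 0, 0.02)
  r <- pmax(r, 0.2)
  oto_contour(cbind(r * cos(th), r * sin(th)))
}

# Arc-length coordinate of each point along a source polygon: the oracle
# for equal arc spacing.  Each query point must lie on a polygon edge.
arc_positions <- function(source_xy, pts) {
  closed <- rbind(source_xy, source_xy[1, ])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  cum <- c(0, cumsum(seg))
  apply(pts, 1, function(p) {
    best <- Inf; pos <- NA_real_
    for (e in seq_len(nrow(closed) - 1)) {
      a <- closed[e, ]; b <- closed[e + 1, ]
      ab <- b - a
      t <- sum((p - a) * ab) / sum(ab^2)
      t <- min(max(t, 0), 1)
      d <- sqrt(sum((a + t * ab - p)^2))
      if (d < best) { best <- d; pos <- cum[e] + t * seg[e] }
    }
    pos
  })
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Five planted otolith shape families spanning the observed morphotype
# axes: rostrum elevation (upper vs lower), antirostrum prominence and
# notch depth, width, posterior angularity.
morphotype_families <- function() {
  list(
    M1 = shape_params(rostrum_elevation =  0.05, antirostrum_amp = 0.18,
                      notch_depth = 0.15, base_semi_minor = 1.15),
    M2 = shape_params(rostrum_elevation =  0.25, antirostrum_amp = 0.06,
                      notch_depth = 0.06),
    M3 = shape_params(rostrum_elevation = -0.25, antirostrum_amp = 0.06,
                      notch_depth = 0.06),
    M4 = shape_params(rostrum_elevation =  0.25, antirostrum_amp = 0.20,
                      notch_depth = 0.12, base_semi_minor = 1.35),
    M5 = shape_params(rostrum_elevation = -0.25, antirostrum_amp = 0.20,
                      notch_depth = 0.15))
}

# Signature -> scale-4 wavelet feature matrix for a dataset, the
# front half of the pipeline used repeatedly in tests.
dataset_features <- function(ds, n_points = 512, scale = 4) {
  sigs <- t(vapply(ds$contours, function(ct)
    shape_signature(resample_equidistant(ct, n_points))$distances,
    numeric(n_points)))
  t(apply(sigs, 1, function(s)
    as.numeric(select_scale(atrous_decompose(s), scale))))
}

cheap_classifier <- function(repeats = 1, seed = 7)
  classifier_config(hidden_units_grid = c(3, 6), repeats = repeats,
                    inner_folds = 3, seed = seed)

# Independent sum-of-squares oracle used for enumeration cross-checks.
oracle_F <- function(D, groups) {
  D2 <- as.matrix(D)^2
  N <- nrow(D2)
  groups <- as.factor(groups)
  a <- nlevels(groups)
  ss_tot <- sum(D2[upper.tri(D2)]) / N
  ss_w <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    pairs <- combn(idx, 2)
    ss_w <- ss_w + sum(D2[cbind(pairs[1, ], pairs[2, ])]) / length(idx)
  }
  ((ss_tot - ss_w) / (a - 1)) / (ss_w / (N - a))
}

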