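test_that("polygon centroid matches closed forms and a raster oracle", {
  sq <- oto_contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(unname(polygon_centroid(sq)), c(0.5, 0.5))
  tri <- oto_contour(rbind(c(0, 0), c(3, 0), c(0, 3)))
  expect_equal(unname(polygon_centroid(tri)), c(1, 1))
  poly <- star_polygon(3)
  mask <- render_binary_image(poly, 512)
  fg <- which(mask$values > 0, arr.ind = TRUE)
  raster_ctr <- c(mean(mask$x[fg[, 1]]), mean(mask$y[fg[, 2]]))
  expect_lt(max(abs(unname(polygon_centroid(poly)) - raster_ctr)), 1e-3)
  degenerate <- rbind(c(0, 0), c(1, 1), c(2, 2))
  expect_error(polygon_centroid(oto_contour(degenerate)), "degenerate")
})

test_that("equidistant resampling hits closed forms on circle and square", {
  rs <- resample_equidistant(circle_contour(4096), 512)
  radii <- sqrt(rowSums(rs$vertices^2))
  expect_true(all(abs(radii - 1) < 1e-6))
  gaps <- sqrt(rowSums((rs$vertices - rs$vertices[c(2:512, 1), ])^2))
  expect_lt(diff(range(gaps)) / mean(gaps), 1e-9)

  sq <- oto_contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  rs <- resample_equidistant(sq, 512)
  gaps <- sqrt(rowSums((rs$vertices - rs$vertices[c(2:512, 1), ])^2))
  expect_equal(gaps, rep(4 / 512, 512), tolerance = 1e-12)
  on_bottom <- sum(abs(rs$vertices[, 2]) < 1e-12 &
                     rs$vertices[, 1] < 1 - 1e-12)
  expect_equal(on_bottom, 128)
  expect_error(resample_equidistant(sq, 2), "at least 3")
})

test_that("resampled points sit at equal arc positions on the source polygon", {
  src <- ellipse_contour(2, 1, n = 4096)
  rs <- resample_equidistant(src, 512)
  s <- arc_positions(src$vertices, rs$vertices)
  closed <- rbind(src$vertices, src$vertices[1, ])
  L <- sum(sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2))
  expect_equal(s, (seq_len(512) - 1) * L / 512, tolerance = 1e-6)
})

test_that("signature normalisation, start point and invariances behave", {
  ell <- ellipse_contour(2, 1, n = 4096)
  # the two major-axis vertices tie for farthest point
  expect_warning(sig <- shape_signature(resample_equidistant(ell, 512)),
                 "tied farthest")
  expect_length(sig$distances, 512)
  expect_equal(mean(sig$distances), 1, tolerance = 1e-12)
  expect_equal(which.max(sig$distances), 1)
  # start point lies on the major axis
  expect_lt(abs(resample_equidistant(ell, 512)$vertices[sig$start_index, 2]), 1e-6)
  # symmetric under index reversal (the ellipse is mirror symmetric)
  rev_sig <- c(sig$distances[1], rev(sig$distances[-1]))
  expect_equal(sig$distances, rev_sig, tolerance = 1e-9)

  base <- star_polygon(11)
  s0 <- shape_signature(resample_equidistant(base, 512))$distances
  shifted <- oto_contour(sweep(base$vertices, 2, c(13.7, -4.2), "+"))
  expect_equal(shape_signature(resample_equidistant(shifted, 512))$distances,
               s0, tolerance = 1e-9)
  scaled <- oto_contour(base$vertices * 10)
  expect_equal(shape_signature(resample_equidistant(scaled, 512))$distances,
               s0, tolerance = 1e-12)
  rolled <- oto_contour(base$vertices[c(100:256, 1:99), ])
  expect_equal(shape_signature(resample_equidistant(rolled, 512))$distances,
               s0, tolerance = 1e-6)
})

test_that("circle signature is identically 1 and ties are reported", {
  expect_warning(
    sig <- shape_signature(resample_equidistant(circle_contour(512), 512)),
    "tied farthest")
  expect_equal(sig$distances, rep(1, 512), tolerance = 1e-9)
})

test_that("canonical orientation mirrors right otoliths and is an involution", {
  left <- star_polygon(5)
  expect_equal(canonical_orientation(left)$vertices, left$vertices)

  right <- oto_contour(cbind(-left$vertices[, 1], left$vertices[, 2]),
                       side = "right")
  once <- canonical_orientation(right)
  expect_equal(once$side, "left")
  # mirroring the mirrored contour again restores the original point set
  back <- canonical_orientation(
    oto_contour(cbind(-once$vertices[, 1], once$vertices[, 2]), side = "right"))
  expect_equal(sort(back$vertices[, 1]), sort(once$vertices[, 1]),
               tolerance = 1e-12)
  # a mirrored otolith yields the same signature as its original
  s_left <- shape_signature(resample_equidistant(left, 512))$distances
  s_right <- shape_signature(resample_equidistant(once, 512))$distances
  expect_equal(s_right, s_left, tolerance = 1e-3)

  unknown <- oto_contour(left$vertices, side = NA)
  expect_error(canonical_orientation(unknown), "unknown")
  expect_silent(canonical_orientation(unknown, assume_left = TRUE))
})

test_that("contour extraction recovers a disk and prefers the dominant blob", {
  n <- 121
  m <- outer(seq_len(n), seq_len(n),
             function(i, j) as.numeric((i - 61)^2 + (j - 61)^2 < 50^2))
  ct <- extract_contour(m)
  radii <- sqrt((ct$vertices[, 1] - 61)^2 + (ct$vertices[, 2] - 61)^2)
  expect_true(all(abs(radii - 50) <= 1))
  x <- ct$vertices[, 1]; y <- ct$vertices[, 2]
  sa <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  expect_gt(sa, 0)  # counterclockwise

  two <- matrix(0, 80, 80)
  two[10:45, 10:45] <- 1            # ~1296 px blob
  two[60:62, 60:62] <- 1            # 9 px blob
  big <- extract_contour(two)
  expect_true(all(big$vertices[, 1] < 50))
  expect_error(extract_contour(matrix(0, 20, 20)), "empty mask")
})

test_that("otolith length reads the anteroposterior extent in mm", {
  expect_equal(otolith_length(ellipse_contour(2, 1)), 4, tolerance = 1e-6)
  left <- star_polygon(9)
  mirrored <- canonical_orientation(
    oto_contour(cbind(-left$vertices[, 1], left$vertices[, 2]), side = "right"))
  expect_equal(otolith_length(mirrored), otolith_length(left), tolerance = 1e-9)
  px <- oto_contour(left$vertices, units = "px")
  expect_error(otolith_length(px), "unknown scale")
  px$scale <- 0.01
  expect_equal(otolith_length(px), 0.01 * otolith_length(left))
})

test_that("render -> extract -> signature round trip stays within 1%", {
  set.seed(42)
  ct <- generate_contour(shape_params())
  src_sig <- shape_signature(resample_equidistant(ct, 512))$distances
  mask <- render_binary_image(ct, 256)
  rt <- resample_equidistant(extract_contour(mask), 512)
  rt_sig <- shape_signature(rt)$distances
  expect_lt(mean(abs(rt_sig - src_sig)), 0.01)
})
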