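test_that("zero-amplitude parameters reproduce the base ellipse", {
  p <- shape_params(rostrum_amp = 0, antirostrum_amp = 0, notch_depth = 0,
                    posterior_angularity = 0, irregularity_sd = 0)
  ct <- generate_contour(p)
  th <- atan2(ct$vertices[, 2], ct$vertices[, 1])
  a <- p$base_semi_major; b <- p$base_semi_minor
  expected_r <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  expect_equal(sqrt(rowSums(ct$vertices^2)), expected_r, tolerance = 1e-9)
})

test_that("rostrum amplitude raises the maximum centroid distance", {
  base <- shape_params(rostrum_amp = 0, irregularity_sd = 0)
  bump <- shape_params(rostrum_amp = 0.3, irregularity_sd = 0)
  expect_gt(measure_rostrum_prominence(generate_contour(bump)),
            measure_rostrum_prominence(generate_contour(base)))
})

test_that("the notch radial minimum is non-increasing in notch depth", {
  min_in_notch_sector <- function(depth) {
    ct <- generate_contour(shape_params(notch_depth = depth, irregularity_sd = 0))
    th <- atan2(ct$vertices[, 2], ct$vertices[, 1])
    r <- sqrt(rowSums(ct$vertices^2))
    min(r[th > 0.25 & th < 0.65])
  }
  mins <- vapply(seq(0, 0.25, by = 0.05), min_in_notch_sector, numeric(1))
  expect_true(all(diff(mins) <= 1e-12))
})

test_that("extreme parameters are rejected as self-intersecting", {
  expect_error(generate_contour(shape_params(notch_depth = 2, irregularity_sd = 0)),
               "rejected")
  expect_error(generate_contour(shape_params(), n_vertices = 512), "1024")
  expect_error(shape_params(rostrum_amp = -1), ">= 0")
})

test_that("population generation is reproducible and honours zero spread", {
  spec <- population_spec("P", 5, shape_params(irregularity_sd = 0),
                          between_individual_sd = 0, size_sd = 0, seed = 3)
  ds <- generate_population(spec)
  expect_length(ds$contours, 5)
  for (i in 2:5) expect_equal(ds$contours[[i]]$vertices, ds$contours[[1]]$vertices)
  ds2 <- generate_population(spec)
  expect_identical(ds, ds2)
  # with size spread, shape (signature) is identical but scale varies
  specv <- population_spec("P", 4, shape_params(irregularity_sd = 0),
                           between_individual_sd = 0, size_sd = 0.3, seed = 4)
  dsv <- generate_population(specv)
  sigs <- lapply(dsv$contours, function(ct)
    shape_signature(resample_equidistant(ct, 512))$distances)
  for (i in 2:4) expect_equal(sigs[[i]], sigs[[1]], tolerance = 1e-9)
  expect_gt(diff(range(dsv$sizes)), 0)
})

test_that("otolith lengths match the requested truncated normal", {
  spec <- population_spec("P", 300, size_mean = 4.1, size_sd = 0.25, seed = 9)
  ds <- generate_population(spec)
  expect_true(all(ds$sizes > 0))
  expect_equal(mean(ds$sizes), 4.1, tolerance = 0.05)
  expect_equal(vapply(ds$contours, otolith_length, numeric(1)), ds$sizes,
               tolerance = 1e-9)
})

test_that("planted allometry yields a positive size-prominence correlation", {
  spec <- population_spec("P", 200, between_individual_sd = 0.01,
                          allometry_slope = c(rostrum_amp = 0.3),
                          size_sd = 0.3, seed = 12)
  ds <- generate_population(spec)
  prom <- vapply(ds$contours, measure_rostrum_prominence, numeric(1))
  expect_gt(cor(ds$sizes, prom), 0.3)
})

test_that("metapopulations concatenate deterministically and reject duplicates", {
  specs <- list(population_spec("A", 4, seed = 1), population_spec("B", 5, seed = 1))
  ds <- generate_metapopulation(specs, seed = 2)
  expect_length(ds$contours, 9)
  expect_equal(unname(table(ds$labels)[c("A", "B")]), c(4L, 5L), ignore_attr = TRUE)
  expect_identical(ds, generate_metapopulation(specs, seed = 2))
  expect_false(identical(ds$contours[[1]]$vertices,
                         generate_metapopulation(specs, seed = 3)$contours[[1]]$vertices))
  expect_error(generate_metapopulation(list(population_spec("A", 2),
                                            population_spec("A", 2))),
               "duplicate")
  expect_error(generate_metapopulation(specs[1]), "at least 2")
})

test_that("the default 11-river design sums to 1141 individuals", {
  specs <- shad_metapopulation_spec()
  expect_length(specs, 11)
  expect_equal(sum(vapply(specs, `[[`, integer(1), "n")), 1141)
  # a scaled-down draw of the two end members reflects the planted gradient
  small <- lapply(specs[c("STL", "STJ")], function(s) { s$n <- 8L; s })
  ds <- generate_metapopulation(small, seed = 6)
  ang <- vapply(ds$contours, measure_rostrum_angle, numeric(1))
  expect_gt(mean(ang[ds$labels == "STL"]), mean(ang[ds$labels == "STJ"]))
})

test_that("a rostrum-elevation gradient shows up monotonically in geometry", {
  elevs <- seq(0.3, -0.3, length.out = 5)
  specs <- lapply(seq_along(elevs), function(i)
    population_spec(paste0("P", i), 10,
                    shape_params(rostrum_elevation = elevs[i]),
                    between_individual_sd = 0.01, seed = i))
  ds <- generate_metapopulation(specs, seed = 13)
  ang <- vapply(ds$contours, measure_rostrum_angle, numeric(1))
  means <- tapply(ang, ds$labels, mean)[paste0("P", 1:5)]
  expect_true(all(diff(means) < 0))
})

test_that("every generated polygon is simple", {
  set.seed(77)
  for (i in 1:5) {
    ct <- generate_contour(shape_params(irregularity_sd = 0.05))
    expect_true(otoshape:::is_simple_polygon(ct$vertices))
  }
})

test_that("rasterisation matches the analytic disk area and flags low resolution", {
  mask <- render_binary_image(circle_contour(2048), 256)
  expect_equal(sum(mask$values), pi * 256^2, tolerance = 0.01)
  # an open ring whose thin opening closes at coarse resolution, turning
  # the region non-simply-connected (outer boundary + hole)
  tho <- seq(0.06, 2 * pi - 0.06, length.out = 800) + pi / 4
  ring <- oto_contour(rbind(cbind(3 * cos(tho), 3 * sin(tho)),
                            cbind(2 * cos(rev(tho)), 2 * sin(rev(tho)))))
  expect_error(render_binary_image(ring, 2), "resolution too low")
  expect_no_error(render_binary_image(ring, 64))
  expect_error(oto_contour(matrix(numeric(0), 0, 2)), "at least 3")
})
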