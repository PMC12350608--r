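# Brute-force Lance-Williams ward.D oracle: agglomerate from the raw
# Euclidean distances (no squaring), lowest-index pair first on ties.
oracle_ward <- function(X) {
  D <- as.matrix(dist(X))
  n <- nrow(D)
  sizes <- rep(1, n)
  active <- seq_len(n)
  members <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  partitions <- list()
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bh <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      d <- D[active[ii], active[jj]]
      if (d < bh - 1e-12) { bh <- d; best <- c(ii, jj) }
    }
    i <- active[best[1]]; j <- active[best[2]]
    heights[step] <- bh
    # ward.D update of distances from the merged cluster to the rest
    for (kk in setdiff(active, c(i, j))) {
      ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[kk]
      D[i, kk] <- D[kk, i] <-
        ((ni + nk) * D[i, kk] + (nj + nk) * D[j, kk] - nk * D[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- sizes[i] + sizes[j]
    members[[i]] <- c(members[[i]], members[[j]])
    active <- setdiff(active, j)
    part <- integer(n)
    for (a in seq_along(active)) part[members[[active[a]]]] <- a
    partitions[[step]] <- part
  }
  list(heights = heights, partitions = partitions)
}

test_that("ward clustering matches the Lance-Williams recurrence oracle", {
  set.seed(14)
  X <- matrix(rnorm(10), 5, 2)
  hc <- ward_cluster(X)
  oracle <- oracle_ward(X)
  expect_equal(sort(hc$height), sort(oracle$heights), tolerance = 1e-10)
  for (k in 1:4) {
    got <- cut_tree(hc, k)
    want <- oracle$partitions[[5 - k]]
    expect_equal(ari(got, want), 1)
  }
})

test_that("merge heights are monotone and degenerate data give zero heights", {
  set.seed(15)
  X <- matrix(rnorm(60), 20, 3)
  hc <- ward_cluster(X)
  expect_true(all(diff(hc$height) >= -1e-12))
  same <- matrix(1, 6, 2)
  expect_equal(ward_cluster(same)$height, rep(0, 5))
  expect_error(ward_cluster(matrix(1, 1, 2)), "at least 2")
})

test_that("tree cutting covers the trivial cuts and planted blobs", {
  set.seed(16)
  X <- rbind(matrix(rnorm(20, 0, 0.3), ncol = 2),
             matrix(rnorm(20, 6, 0.3), ncol = 2))
  truth <- rep(1:2, each = 10)
  hc <- ward_cluster(X)
  expect_equal(cut_tree(hc, 1), rep(1L, 20))
  expect_equal(sort(unique(cut_tree(hc, 20))), 1:20)
  expect_equal(ari(cut_tree(hc, 2), truth), 1)
  expect_error(cut_tree(hc, 0), "between 1")
  expect_error(cut_tree(hc, 21), "between 1")
  # four far-apart points in two tight pairs: the last merge joins the pairs
  P <- rbind(c(0, 0), c(0.1, 0), c(10, 0), c(10.1, 0))
  expect_equal(ari(cut_tree(ward_cluster(P), 2), c(1, 1, 2, 2)), 1)
})

test_that("cut assignments are nested and row-order invariant", {
  set.seed(17)
  X <- matrix(rnorm(90), 30, 3)
  hc <- ward_cluster(X)
  for (k in 2:6) {
    a_k <- cut_tree(hc, k)
    a_k1 <- cut_tree(hc, k + 1)
    # refining k -> k+1 splits exactly one cluster
    crossed <- table(a_k, a_k1)
    split_counts <- rowSums(crossed > 0)
    expect_equal(sum(split_counts == 2), 1)
    expect_true(all(split_counts %in% 1:2))
  }
  ord <- sample(30)
  hc2 <- ward_cluster(X[ord, ])
  expect_equal(ari(cut_tree(hc2, 4), cut_tree(hc, 4)[ord]), 1)
})

test_that("composition tables give per-population proportions and class sums", {
  one <- morphotype_composition(rep(1, 8), rep("R", 8))
  expect_equal(unname(one$proportions[1, 1]), 1)
  two <- morphotype_composition(rep(c(1, 2), c(5, 15)), rep("R", 20))
  expect_equal(unname(two$proportions[, 1]), c(0.25, 0.75))
  mt <- c(1, 1, 2, 2, 3, 3)
  pop <- rep(c("N", "S"), 3)
  full <- morphotype_composition(
    mt, pop,
    rostrum_map = c(`1` = "lower", `2` = "upper", `3` = "lower"),
    antirostrum_map = c(`1` = "well", `2` = "less", `3` = "less"))
  expect_equal(colSums(full$proportions), c(N = 1, S = 1))
  expect_equal(colSums(full$rostrum_proportions), c(N = 1, S = 1))
  expect_equal(unname(full$rostrum_proportions["lower", ]), c(2 / 3, 2 / 3))
  expect_error(morphotype_composition(mt, pop, rostrum_map = c(`1` = "lower")),
               "unmapped")
  expect_error(morphotype_composition(1:3, rep("R", 4)), "same length")
})

test_that("planted family mixtures are recovered within 0.1", {
  fams <- morphotype_families()[c("M2", "M3")]
  specs <- list(
    population_spec("N", 60, families = fams, family_weights = c(0.8, 0.2),
                    between_individual_sd = 0.02, seed = 1),
    population_spec("S", 60, families = fams, family_weights = c(0.2, 0.8),
                    between_individual_sd = 0.02, seed = 2))
  ds <- generate_metapopulation(specs, seed = 30)
  feats <- dataset_features(ds)
  sc <- pca_covariance(feats)$scores[, 1:3]
  assign <- cut_tree(ward_cluster(sc), 2)
  comp <- morphotype_composition(assign, ds$labels)
  planted <- morphotype_composition(ds$true_morphotype, ds$labels)
  # align discovered clusters to planted families by majority overlap
  overlap <- table(assign, ds$true_morphotype)
  map <- colnames(overlap)[apply(overlap, 1, which.max)]
  expect_setequal(map, c("M2", "M3"))
  aligned <- comp$proportions[match(c("M2", "M3"), map), ]
  expect_lt(max(abs(aligned - planted$proportions[c("M2", "M3"), ])), 0.1)
})

test_that("the morphotype separation test warns about circularity", {
  set.seed(18)
  X <- rbind(matrix(rnorm(30, 0, 0.4), ncol = 3),
             matrix(rnorm(30, 4, 0.4), ncol = 3))
  assign <- cut_tree(ward_cluster(X), 2)
  expect_warning(res <- morphotype_separation_test(X, assign, n_perm = 99,
                                                   seed = 1),
                 "anti-conservative")
  expect_match(res$circularity_note, "inflated")
  ref <- permanova_global(manhattan_distances(X), assign, n_perm = 99, seed = 1)
  expect_equal(res$pseudo_F, ref$pseudo_F)
  expect_equal(res$p_value, ref$p_value)
})

test_that("silhouette profile prefers the true cluster count", {
  set.seed(19)
  X <- rbind(cbind(rnorm(20, 0, 0.3), rnorm(20, 0, 0.3)),
             cbind(rnorm(20, 5, 0.3), rnorm(20, 5, 0.3)),
             cbind(rnorm(20, 0, 0.3), rnorm(20, 5, 0.3)))
  prof <- silhouette_profile(X, 2:6)
  expect_equal(prof$k[which.max(prof$mean_silhouette)], 3)
})
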