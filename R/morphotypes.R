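#' Ward hierarchical clustering of shape scores
#'
#' Agglomerative clustering with the "ward.D" criterion: the
#' Lance-Williams ward update applied to the Euclidean input
#' dissimilarities as-is (no squaring before the update), the classic
#' variant used for otolith morphotype discovery.  Merge heights are
#' monotone non-decreasing.
#'
#' @param X numeric score matrix (>= 2 rows, no missing values).
#' @return An [stats::hclust] dendrogram.
#' @export
ward_cluster <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("clustering needs at least 2 observations")
  if (any(!is.finite(X))) stop("score matrix contains non-finite values")
  stats::hclust(stats::dist(X), method = "ward.D")
}

#' Cut a dendrogram into k morphotypes
#'
#' Undoes the last `k - 1` merges and labels the resulting clusters
#' `1..k` in order of first appearance in the input rows, so labels are
#' stable under re-runs on the same data.
#'
#' @param dendrogram an [stats::hclust] object.
#' @param k number of clusters, `1 <= k <= N`.
#' @return Integer vector of morphotype assignments.
#' @export
cut_tree <- function(dendrogram, k) {
  n <- length(dendrogram$order)
  if (k < 1 || k > n) stop(sprintf("`k` must be between 1 and %d", n))
  raw <- stats::cutree(dendrogram, k = k)
  relabel_first_appearance(raw)
}

relabel_first_appearance <- function(x) {
  map <- setNames(seq_along(unique(x)), unique(x))
  unname(map[as.character(x)])
}

#' Morphotype composition by population
#'
#' Cross-tabulates morphotype assignments against population labels as
#' within-population proportions (each population column sums to 1).
#' Optional morphotype-to-class maps aggregate morphotypes into
#' rostrum-position ("upper"/"lower") and antirostrum-development
#' ("less"/"well") classes; the maps are user-supplied because cluster
#' identities permute across runs.
#'
#' @param assignments morphotype id per individual.
#' @param populations population label per individual (same length).
#' @param rostrum_map,antirostrum_map optional named vectors mapping each
#'   morphotype id (as character) to a class label; every observed
#'   morphotype must be mapped.
#' @return List of class `oto_morphotable`: `proportions` (morphotype x
#'   population), `counts`, and (if mapped) `rostrum_proportions`,
#'   `antirostrum_proportions`.
#' @export
morphotype_composition <- function(assignments, populations,
                                   rostrum_map = NULL, antirostrum_map = NULL) {
  if (length(assignments) != length(populations))
    stop("`assignments` and `populations` must have the same length")
  counts <- table(morphotype = assignments, population = populations)
  prop <- sweep(counts, 2, colSums(counts), "/")
  aggregate_classes <- function(map, what) {
    if (is.null(map)) return(NULL)
    mts <- rownames(counts)
    missing <- setdiff(mts, names(map))
    if (length(missing))
      stop(sprintf("unmapped morphotype(s) in %s map: %s", what,
                   paste(missing, collapse = ", ")))
    cls <- factor(map[mts])
    agg <- apply(prop, 2, function(col) tapply(col, cls, sum))
    matrix(agg, nrow = nlevels(cls),
           dimnames = list(levels(cls), colnames(prop)))
  }
  structure(list(proportions = unclass(prop), counts = unclass(counts),
                 rostrum_proportions = aggregate_classes(rostrum_map, "rostrum"),
                 antirostrum_proportions = aggregate_classes(antirostrum_map, "antirostrum")),
            class = "oto_morphotable")
}

#' @export
print.oto_morphotable <- function(x, ...) {
  cat("Morphotype proportions by population:\n")
  print(round(x$proportions, 3))
  invisible(x)
}

#' PERMANOVA among morphotypes (with circularity caveat)
#'
#' Tests separation among cluster-derived morphotypes by delegating to
#' [permanova_global()] with the morphotype assignments as groups.
#' Because the labels were derived from the same data being tested, the
#' p value is anti-conservative by construction; the result carries an
#' explicit circularity note and a warning is raised.
#'
#' @param X score matrix the morphotypes were clustered on.
#' @param assignments morphotype id per row.
#' @inheritParams permanova_global
#' @return An `oto_permanova` with an added `circularity_note`.
#' @export
morphotype_separation_test <- function(X, assignments, n_perm = 9999,
                                       seed = NULL) {
  res <- permanova_global(manhattan_distances(X), assignments,
                          n_perm = n_perm, seed = seed)
  res$circularity_note <- paste(
    "morphotype labels were derived from the same data under test;",
    "the permutation p value is inflated toward significance")
  warning("testing cluster-derived labels on the data that produced them: p is anti-conservative")
  res
}

#' Mean silhouette width across candidate cluster counts
#'
#' Supports the choice of the morphotype count by reporting the mean
#' silhouette width of the Ward partition for each k in `k_range`.
#'
#' @param X score matrix.
#' @param k_range candidate cluster counts (default 2:10).
#' @return Data frame (`k`, `mean_silhouette`).
#' @export
silhouette_profile <- function(X, k_range = 2:10) {
  X <- as.matrix(X)
  d <- stats::dist(X)
  hc <- ward_cluster(X)
  data.frame(k = k_range, mean_silhouette = vapply(k_range, function(k) {
    sil <- cluster::silhouette(cut_tree(hc, k), d)
    mean(sil[, "sil_width"])
  }, numeric(1)))
}
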