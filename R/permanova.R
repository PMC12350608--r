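#' Manhattan distance matrix
#'
#' Pairwise city-block distances `d_ij = sum_m |x_im - x_jm|`, the metric
#' used for the multivariate dispersion tests in this pipeline.
#'
#' @param X numeric matrix, one observation per row, finite entries.
#' @return A `dist` object with attribute `metric = "manhattan"`.
#' @export
manhattan_distances <- function(X) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("distance input contains non-finite entries")
  d <- stats::dist(X, method = "manhattan")
  attr(d, "metric") <- "manhattan"
  d
}

# Sum-of-squares partition on a squared distance matrix for a grouping.
# SS_total = (1/N) sum_{i<j} d_ij^2 ; SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2
ss_within <- function(D2, groups) {
  s <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    s <- s + sum(D2[idx, idx]) / (2 * length(idx))
  }
  s
}

pseudo_F <- function(ss_among, ss_with, a, N) {
  (ss_among / (a - 1)) / (ss_with / (N - a))
}

#' Global PERMANOVA (one-way, permutation test)
#'
#' Permutational multivariate analysis of variance from its definition:
#' the total sum of squared inter-point distances is partitioned into
#' among- and within-group parts,
#' `SS_total = (1/N) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`,
#' `SS_among = SS_total - SS_within`, and the pseudo-F statistic
#' `F = (SS_among / (a-1)) / (SS_within / (N-a))` is referred to its
#' permutation distribution under unrestricted random relabelling.  The
#' observed statistic is included in the null set, so
#' `p = (#(F* >= F_obs) + 1) / (n_perm + 1)` and `p > 0` always; ties
#' `F* = F_obs` count as exceedances (conservative).
#'
#' With `exhaustive = TRUE` (small N only) all `N!` relabellings are
#' enumerated instead and `p` is the exact fraction of arrangements with
#' `F* >= F_obs` (the identity arrangement included).
#'
#' @param D a `dist` or square distance matrix (e.g.
#'   [manhattan_distances()]).
#' @param groups group label per observation; >= 2 groups, each with
#'   >= 2 members.
#' @param n_perm number of random permutations (default 9999).
#' @param seed integer seed for the permutation stream (logged in the
#'   result).
#' @param exhaustive enumerate all relabellings instead of sampling
#'   (requires N <= 9).
#' @return An object of class `oto_permanova` with `pseudo_F`,
#'   `df_among`, `df_within`, `ss` (total/among/within), `p_value`,
#'   `n_permutations`, `seed`, `exhaustive`.
#' @export
permanova_global <- function(D, groups, n_perm = 9999, seed = NULL,
                             exhaustive = FALSE) {
  D <- as.matrix(D)
  groups <- droplevels(as.factor(groups))
  N <- nrow(D)
  if (length(groups) != N) stop("`groups` must match the distance matrix")
  a <- nlevels(groups)
  if (a < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  D2 <- D^2
  ss_tot <- sum(D2[upper.tri(D2)]) / N
  ss_w <- ss_within(D2, groups)
  ss_a <- ss_tot - ss_w
  Fobs <- if (ss_w <= 0) Inf else pseudo_F(ss_a, ss_w, a, N)
  if (exhaustive) {
    if (N > 9) stop("exhaustive enumeration is limited to N <= 9")
    perms <- all_permutations(N)
    Fstar <- apply(perms, 1, function(p) {
      sw <- ss_within(D2, groups[p])
      if (sw <= 0) Inf else pseudo_F(ss_tot - sw, sw, a, N)
    })
    p <- mean(Fstar >= Fobs)
    nper <- nrow(perms)
  } else {
    Fstar <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        gp <- groups[sample.int(N)]
        sw <- ss_within(D2, gp)
        if (sw <= 0) Inf else pseudo_F(ss_tot - sw, sw, a, N)
      }, numeric(1))
    })
    p <- (sum(Fstar >= Fobs) + 1) / (n_perm + 1)
    nper <- n_perm
  }
  structure(list(pseudo_F = Fobs, df_among = a - 1L, df_within = N - a,
                 ss = c(total = ss_tot, among = ss_a, within = ss_w),
                 p_value = p, n_permutations = nper, seed = seed,
                 exhaustive = exhaustive),
            class = "oto_permanova")
}

# All N! permutations of 1:n as rows (n <= 9 guard upstream).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row:(row + nrow(sub) - 1), ] <- cbind(k, matrix(rest[sub], nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

#' @export
print.oto_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g on (%d, %d) df, p = %.4g (%s%d permutations)\n",
              x$pseudo_F, x$df_among, x$df_within, x$p_value,
              if (x$exhaustive) "exhaustive, " else "", x$n_permutations))
  if (!is.null(x$circularity_note)) cat("  note:", x$circularity_note, "\n")
  invisible(x)
}

#' Pairwise PERMANOVA with multiplicity correction
#'
#' Runs [permanova_global()] on every pair of groups (each pair's
#' submatrix re-permuted independently) and adjusts the raw p values,
#' by default with the Bonferroni correction
#' `p_adj = min(1, p * n_pairs)`.
#'
#' @inheritParams permanova_global
#' @param correction `"bonferroni"` (default) or any method of
#'   [stats::p.adjust()].
#' @return Data frame with `group1`, `group2`, `pseudo_F`, `p`,
#'   `p_adjusted` (one row per pair; `C(a, 2)` rows for `a` groups).
#' @export
permanova_pairwise <- function(D, groups, n_perm = 9999,
                               correction = "bonferroni", seed = NULL) {
  D <- as.matrix(D)
  groups <- droplevels(as.factor(groups))
  lev <- levels(groups)
  if (length(lev) < 2) stop("need at least 2 groups")
  pairs <- utils::combn(lev, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    idx <- which(groups %in% c(g1, g2))
    fit <- permanova_global(D[idx, idx], groups[idx], n_perm = n_perm,
                            seed = derive_seed(seed, i))
    data.frame(group1 = g1, group2 = g2, pseudo_F = fit$pseudo_F,
               p = fit$p_value)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- if (correction == "bonferroni") {
    pmin(1, out$p * nrow(out))
  } else stats::p.adjust(out$p, method = correction)
  out
}
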