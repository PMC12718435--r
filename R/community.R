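#' Hierarchical clustering of sites
#'
#' Agglomerative clustering of sites by their (scaled) environment or by
#' their (transformed) assemblages. The default Euclidean + Ward pairing
#' matches the distance geometry the rest of the workflow uses: Euclidean
#' distance on Hellinger-transformed assemblages is the Hellinger distance.
#'
#' @param tbl Site-keyed tibble (environment or community values).
#' @param metric Distance metric passed to [stats::dist()].
#' @param linkage Linkage method passed to [stats::hclust()]
#'   (default `"ward.D2"`).
#' @param k Number of clusters to cut the tree into.
#' @return A `site_clusters` object: `tree` (hclust), `assignment` tibble,
#'   mean silhouette width.
#' @export
cluster_sites <- function(tbl, metric = "euclidean", linkage = "ward.D2", k = 3) {
  m <- comm_matrix(tbl, "site table")
  n <- nrow(m)
  if (n < 2) abort("need at least 2 sites to cluster")
  if (k > n) abort(sprintf("k = %d exceeds the number of sites (%d)", k, n))
  d <- stats::dist(m, method = metric)
  tree <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(tree, k = k)
  sil <- if (k > 1 && k < n) {
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  } else NA_real_
  structure(list(tree = tree,
                 assignment = tibble::tibble(site = rownames(m),
                                             cluster = as.integer(cl)),
                 k = k, metric = metric, linkage = linkage,
                 silhouette = sil),
            class = "site_clusters")
}

#' @export
print.site_clusters <- function(x, ...) {
  cat(sprintf("<site_clusters> %s/%s, k = %d, mean silhouette %.3f\n",
              x$metric, x$linkage, x$k, x$silhouette))
  print(table(x$assignment$cluster))
  invisible(x)
}

#' Export a clustering tree as newick text
#'
#' @param x A `site_clusters` object.
#' @return A single newick string.
#' @export
cluster_newick <- function(x) {
  ape::write.tree(ape::as.phylo(x$tree))
}

#' Bin a gradient into equal-width classes
#'
#' Default 1-unit bins aligned to integer boundaries; used to turn the
#' continuous calibration gradient into site groups for the indicator-species
#' analysis.
#'
#' @param x Numeric vector (e.g. temperature in degC).
#' @param width Class width in the units of `x`.
#' @return A factor with interval labels.
#' @export
gradient_classes <- function(x, width = 1) {
  brk <- seq(floor(min(x) / width) * width,
             ceiling(max(x) / width) * width, by = width)
  cut(x, breaks = brk, include.lowest = TRUE, right = FALSE)
}

indval_stats <- function(Y, groups, combos) {
  lev <- levels(groups)
  Mg <- t(apply(Y, 2, function(y) tapply(y, groups, mean)))  # taxa x groups
  if (length(lev) == 1) Mg <- matrix(Mg, ncol = 1, dimnames = list(colnames(Y), lev))
  denom <- rowSums(Mg)
  res <- lapply(combos, function(cc) {
    in_c <- groups %in% cc
    A <- rowSums(Mg[, cc, drop = FALSE]) / denom
    B <- colSums(Y[in_c, , drop = FALSE] > 0) / sum(in_c)
    list(A = A, B = B, stat = sqrt(A * B))
  })
  stat_m <- vapply(res, `[[`, numeric(ncol(Y)), "stat")
  if (is.null(dim(stat_m))) stat_m <- matrix(stat_m, nrow = ncol(Y))
  best <- apply(stat_m, 1, which.max)
  list(res = res, best = best,
       best_stat = stat_m[cbind(seq_len(ncol(Y)), best)])
}

#' Indicator-species analysis (IndVal)
#'
#' For each taxon and site group: specificity `A` is the group's mean
#' abundance divided by the summed mean abundances over all groups, fidelity
#' `B` is the fraction of the group's sites where the taxon occurs, and the
#' indicator statistic is `sqrt(A * B)`. The best group (optionally the best
#' combination of groups) is reported per taxon with a permutation p value
#' obtained by reshuffling the site labels.
#'
#' @param species Community tibble (relative abundances recommended).
#' @param groups Factor (or vector) of site group labels, aligned with rows.
#' @param n_perm Number of label permutations.
#' @param seed Seed for the permutation stream.
#' @param with_combinations Also consider unions of groups as candidate
#'   indicator targets.
#' @return A tibble: taxon, group, A, B, stat, p.
#' @export
indval <- function(species, groups, n_perm = 999, seed = 1,
                   with_combinations = FALSE) {
  Y <- comm_matrix(species, "species table")
  groups <- droplevels(as.factor(groups))
  if (length(groups) != nrow(Y)) abort("groups must align with the sites")
  if (nlevels(groups) < 2) abort("need at least 2 non-empty groups")
  lev <- levels(groups)
  combos <- as.list(lev)
  if (with_combinations && length(lev) > 2) {
    for (sz in 2:(length(lev) - 1)) {
      combos <- c(combos, utils::combn(lev, sz, simplify = FALSE))
    }
  }
  obs <- indval_stats(Y, groups, combos)
  set.seed(seed)
  exceed <- rep(0L, ncol(Y))
  for (b in seq_len(n_perm)) {
    perm <- indval_stats(Y, sample(groups), combos)
    exceed <- exceed + (perm$best_stat >= obs$best_stat - 1e-12)
  }
  best_combo <- vapply(unname(obs$best),
                       function(i) paste(combos[[i]], collapse = "+"),
                       character(1))
  A <- vapply(seq_len(ncol(Y)), function(k) obs$res[[obs$best[k]]]$A[k], numeric(1))
  B <- vapply(seq_len(ncol(Y)), function(k) obs$res[[obs$best[k]]]$B[k], numeric(1))
  tibble::tibble(taxon = colnames(Y), group = best_combo,
                 A = unname(A), B = unname(B),
                 stat = unname(obs$best_stat),
                 p = (1 + exceed) / (1 + n_perm)) |>
    dplyr::arrange(dplyr::desc(.data$stat))
}
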