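# UPGMA clustering of positional profiles on correlation distance.

#' Cluster positional profiles
#'
#' Computes pairwise distances `d(a, b) = 1 - Pearson(r_a, r_b)` between
#' motif profiles and agglomerates with UPGMA (average linkage).
#' Zero-variance profiles are treated as uncorrelated with everything
#' (distance 1). The leaf order is the standard left-to-right dendrogram
#' traversal.
#'
#' @param profiles List of `positional_profile` objects of equal length
#'   (at least one; a single profile yields a trivial clustering).
#' @return A `profile_clustering` object: list with `motif_ids`,
#'   `distance` (symmetric matrix), `hclust` (the [stats::hclust()] fit,
#'   `NULL` for a single profile), `linkage` (tibble with `step`, `left`,
#'   `right`, `height`, `size`) and `leaf_order` (motif IDs).
#' @export
cluster_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  ids <- vapply(profiles, `[[`, character(1), "motif_id")
  P <- do.call(rbind, lapply(profiles, function(pr) pr$tbl$r))
  rownames(P) <- ids
  if (length(profiles) == 1L) {
    return(structure(list(
      motif_ids = ids,
      distance = matrix(0, 1, 1, dimnames = list(ids, ids)),
      hclust = NULL,
      linkage = tibble(step = integer(0), left = integer(0),
                       right = integer(0), height = numeric(0),
                       size = integer(0)),
      leaf_order = ids
    ), class = "profile_clustering"))
  }
  sds <- apply(P, 1, sd)
  C <- suppressWarnings(cor(t(P)))
  C[is.na(C)] <- 0 # zero-variance rows: uncorrelated
  D <- 1 - C
  D[sds == 0, ] <- 1
  D[, sds == 0] <- 1
  diag(D) <- 0
  hc <- hclust(as.dist(D), method = "average")
  sizes <- integer(nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    sz <- function(v) if (v < 0) 1L else sizes[v]
    sizes[s] <- sz(hc$merge[s, 1]) + sz(hc$merge[s, 2])
  }
  structure(list(
    motif_ids = ids,
    distance = D,
    hclust = hc,
    linkage = tibble(step = seq_len(nrow(hc$merge)),
                     left = hc$merge[, 1], right = hc$merge[, 2],
                     height = hc$height, size = sizes),
    leaf_order = ids[hc$order]
  ), class = "profile_clustering")
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat("<profile_clustering> ", length(x$motif_ids),
      " motifs (UPGMA, 1 - correlation)\n", sep = "")
  cat("  leaf order: ", paste(x$leaf_order, collapse = ", "), "\n", sep = "")
  invisible(x)
}
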