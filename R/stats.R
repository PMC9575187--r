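# Positional enrichment statistics: per-position partial Pearson
# correlation of motif match strength with sequence score, controlling for
# sequence-wide GC content; permutation nulls, confidence bands, p-values,
# Benjamini-Yekutieli correction, the motif-count track and profile
# extrema.

#' Sequence-wide GC ratio
#'
#' `(G + C) / (A + C + G + T)`, case-insensitive; `N` and other ambiguous
#' bases are excluded from numerator and denominator. Sequences with no
#' unambiguous base get 0.5 and are flagged in the `"degenerate"`
#' attribute.
#'
#' @param seq Character vector of DNA sequences.
#' @return Numeric vector in `[0, 1]` with a logical `"degenerate"`
#'   attribute.
#' @export
#' @examples
#' gc_ratio(c("GGCC", "ACGT", "ANGT"))
gc_ratio <- function(seq) {
  stopifnot(is.character(seq), all(nchar(seq) > 0))
  gc <- nchar(gsub("[^GCgc]", "", seq))
  at <- nchar(gsub("[^ATat]", "", seq))
  denom <- gc + at
  degenerate <- denom == 0
  out <- ifelse(degenerate, 0.5, gc / pmax(denom, 1))
  attr(out, "degenerate") <- degenerate
  out
}

#' Partial Pearson correlation of x and y controlling for z
#'
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`. Degenerate
#' cases: zero variance in `x` or `y`, or `|r_xz| = 1` or `|r_yz| = 1`,
#' return 0 with a `"degenerate"` attribute; zero variance in `z` falls
#' back to the plain Pearson correlation of `x` and `y`.
#'
#' @param x,y,z Numeric vectors of equal length `n >= 3`.
#' @return A numeric scalar in `[-1, 1]` (attribute `"degenerate"` set
#'   when the value is a placeholder 0).
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (n < 3L || length(y) != n || length(z) != n) {
    abort("partial_correlation needs three equal-length vectors, n >= 3")
  }
  deg <- function(v) structure(v, degenerate = TRUE)
  if (sd(x) == 0 || sd(y) == 0) return(deg(0))
  if (sd(z) == 0) return(structure(cor(x, y), degenerate = FALSE))
  r_xy <- cor(x, y); r_xz <- cor(x, z); r_yz <- cor(y, z)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) return(deg(0))
  r <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  structure(max(-1, min(1, r)), degenerate = FALSE)
}

# Precompute the per-column quantities that do not change when the score
# vector is permuted (the covariate z stays attached to its sequence, so
# r_xz is fixed). Returns an "engine" for fast repeated profile
# evaluation.
profile_engine <- function(X, z) {
  n <- nrow(X)
  stopifnot(n >= 3L, length(z) == n)
  Xc <- sweep(X, 2, colMeans(X))
  sx <- sqrt(colSums(Xc^2) / (n - 1))
  zc <- z - mean(z)
  sz <- sqrt(sum(zc^2) / (n - 1))
  r_xz <- if (sz > 0) {
    as.vector(crossprod(Xc, zc)) / ((n - 1) * sx * sz)
  } else {
    rep(0, ncol(X))
  }
  r_xz[sx == 0] <- 0
  list(n = n, Xc = Xc, sx = sx, zc = zc, sz = sz, r_xz = r_xz)
}

# Evaluate the positional profile for a score vector y using a
# precomputed engine. Returns list(r, degenerate).
profile_eval <- function(eng, y) {
  n <- eng$n
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2) / (n - 1))
  L <- ncol(eng$Xc)
  if (sy == 0) {
    return(list(r = rep(0, L), degenerate = rep(TRUE, L)))
  }
  r_xy <- as.vector(crossprod(eng$Xc, yc)) / ((n - 1) * eng$sx * sy)
  r_xy[eng$sx == 0] <- 0
  if (eng$sz == 0) {
    r <- r_xy
    degenerate <- eng$sx == 0
    r[degenerate] <- 0
    return(list(r = pmin(1, pmax(-1, r)), degenerate = degenerate))
  }
  r_yz <- sum(yc * eng$zc) / ((n - 1) * sy * eng$sz)
  denom2 <- (1 - eng$r_xz^2) * (1 - r_yz^2)
  degenerate <- eng$sx == 0 | denom2 <= 1e-12
  r <- (r_xy - eng$r_xz * r_yz) / sqrt(pmax(denom2, 1e-300))
  r[degenerate] <- 0
  list(r = pmin(1, pmax(-1, r)), degenerate = degenerate)
}

#' Positional enrichment profile of a motif heatmap
#'
#' At each position column of the smoothed heatmap, the partial Pearson
#' correlation of motif match strength with the sequence scores,
#' controlling for sequence-wide GC ratios. Columns with zero motif-score
#' variance are reported as r = 0 and flagged degenerate (the profile
#' keeps its full length).
#'
#' @param hm A `motif_heatmap`.
#' @param scores Sequence scores aligned to the heatmap rows (defaults to
#'   those stored in the heatmap).
#' @param gc GC ratios aligned to the heatmap rows (defaults stored).
#' @return Numeric vector of length L with a logical `"degenerate"`
#'   attribute.
#' @export
positional_profile <- function(hm, scores = hm$scores, gc = hm$gc) {
  eng <- profile_engine(hm$smoothed, gc)
  res <- profile_eval(eng, scores)
  structure(res$r, degenerate = res$degenerate)
}

#' Permutation null profiles
#'
#' Recomputes the positional profile for `n_perm` uniform random
#' permutations of the score vector. The GC covariate stays attached to
#' its sequence, so the confound structure is preserved under the null;
#' only the score-to-sequence assignment is broken. Deterministic for a
#' fixed seed.
#'
#' @param hm A `motif_heatmap`.
#' @param scores,gc Aligned score and GC vectors (defaults stored in
#'   `hm`).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the permutation stream.
#' @return An `n_perm` x L matrix of null profile values.
#' @export
permutation_null <- function(hm, scores = hm$scores, gc = hm$gc,
                             n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 1)
  eng <- profile_engine(hm$smoothed, gc)
  n <- eng$n
  L <- ncol(hm$smoothed)
  out <- matrix(0, n_perm, L)
  withr::with_seed(as.integer(seed), {
    for (p in seq_len(n_perm)) {
      out[p, ] <- profile_eval(eng, scores[sample.int(n)])$r
    }
  })
  out
}

#' Pointwise confidence bands and permutation p-values
#'
#' Confidence bounds are the pointwise `alpha/2` and `1 - alpha/2`
#' empirical quantiles of the null profiles. P-values are two-sided
#' add-one permutation p-values,
#' `(1 + #\{|null| >= |observed|\}) / (n_perm + 1)`; with
#' `method = "normal"` a normal approximation from the null mean and SD is
#' used instead (finer resolution at small `n_perm`).
#'
#' @param r Observed profile (length L).
#' @param null `n_perm` x L null profile matrix.
#' @param alpha Band level (default 0.05 for a 95% band).
#' @param method `"quantile"` (default) or `"normal"`.
#' @return A tibble with columns `ci_low`, `ci_high`, `null_mean`,
#'   `null_sd`, `p`.
#' @export
profile_significance <- function(r, null, alpha = 0.05,
                                 method = c("quantile", "normal")) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1, ncol(null) == length(r))
  n_perm <- nrow(null)
  qs <- apply(null, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
              names = FALSE)
  null_mean <- colMeans(null)
  null_sd <- apply(null, 2, sd)
  if (method == "quantile") {
    exceed <- colSums(abs(null) >= matrix(abs(r), n_perm, length(r),
                                          byrow = TRUE))
    p <- (1 + exceed) / (n_perm + 1)
  } else {
    z <- abs(r - null_mean) / pmax(null_sd, 1e-12)
    p <- pmin(1, 2 * pnorm(-z))
    p[null_sd == 0 & abs(r - null_mean) < 1e-12] <- 1
  }
  tibble(ci_low = qs[1, ], ci_high = qs[2, ],
         null_mean = null_mean, null_sd = null_sd, p = p)
}

#' Benjamini-Yekutieli correction
#'
#' Step-up false-discovery-rate correction valid under arbitrary
#' dependence, applied to the whole family at once (in the pipeline: all
#' positions of all motifs). Preserves the shape of the input.
#'
#' @param p Numeric vector or matrix of raw p-values in `(0, 1]`.
#' @return Adjusted p-values with the same shape.
#' @export
adjust_by <- function(p) {
  adj <- p.adjust(as.vector(p), method = "BY")
  if (is.matrix(p)) adj <- matrix(adj, nrow(p), ncol(p), dimnames = dimnames(p))
  adj
}

#' Motif count track
#'
#' The number of sequences with an above-threshold motif (raw heatmap
#' value > 0) at each position, plus a centered rolling mean of window `w`
#' with edge shrinkage for display.
#'
#' @param hm A `motif_heatmap`.
#' @param w Smoothing window (defaults to the heatmap's `1 + 2 * margin`).
#' @return A tibble with columns `offset`, `count`, `count_smoothed`.
#' @export
motif_count_track <- function(hm, w = hm$w) {
  counts <- colSums(hm$raw > 0)
  tibble(offset = hm$offsets, count = as.integer(counts),
         count_smoothed = rolling_mean(counts, w))
}

#' Compute the full positional profile for one motif
#'
#' Convenience wrapper that ties together the observed profile, the
#' permutation null, significance and the count track for a single motif
#' heatmap.
#'
#' @param hm A `motif_heatmap`.
#' @param n_perm Number of score permutations.
#' @param seed Seed for the permutation stream.
#' @param alpha Confidence band level.
#' @param method P-value method, see [profile_significance()].
#' @return A `positional_profile` object: list with `motif_id`, a per-
#'   offset tibble `tbl` (`offset`, `r`, `degenerate`, `ci_low`,
#'   `ci_high`, `null_mean`, `null_sd`, `p`, `p_adj`, `count`,
#'   `count_smoothed`), and the run parameters. `p_adj` is `NA` until
#'   [adjust_profiles()] is applied across a motif set.
#' @export
motif_profile <- function(hm, n_perm = 1000, seed = 1, alpha = 0.05,
                          method = c("quantile", "normal")) {
  method <- match.arg(method)
  r <- positional_profile(hm)
  null <- permutation_null(hm, n_perm = n_perm, seed = seed)
  sig <- profile_significance(as.numeric(r), null, alpha, method)
  track <- motif_count_track(hm)
  deg <- attr(r, "degenerate")
  tbl <- tibble(
    offset = hm$offsets,
    r = as.numeric(r),
    degenerate = deg,
    ci_low = sig$ci_low, ci_high = sig$ci_high,
    null_mean = sig$null_mean, null_sd = sig$null_sd,
    p = sig$p, p_adj = NA_real_,
    count = track$count, count_smoothed = track$count_smoothed
  )
  structure(list(motif_id = hm$motif_id, tbl = tbl, n_perm = n_perm,
                 seed = seed, alpha = alpha, method = method),
            class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, ...) {
  ex <- profile_extrema(x)
  cat("<positional_profile> ", x$motif_id, ": ", nrow(x$tbl),
      " positions, ", x$n_perm, " permutations\n", sep = "")
  cat(sprintf("  max r = %.3f at offset %+d; min r = %.3f at offset %+d\n",
              ex$max_r, ex$max_offset, ex$min_r, ex$min_offset))
  invisible(x)
}

#' Apply Benjamini-Yekutieli correction across a set of profiles
#'
#' Corrects jointly over all positions of all motifs (family size =
#' number of motifs x profile length) and writes `p_adj` back into each
#' profile.
#'
#' @param profiles List of `positional_profile` objects.
#' @return The list, with `p_adj` filled in.
#' @export
adjust_profiles <- function(profiles) {
  ps <- unlist(lapply(profiles, function(pr) pr$tbl$p))
  adj <- adjust_by(ps)
  at <- 0L
  for (i in seq_along(profiles)) {
    L <- nrow(profiles[[i]]$tbl)
    profiles[[i]]$tbl$p_adj <- adj[(at + 1L):(at + L)]
    at <- at + L
  }
  profiles
}

#' Extrema of a positional profile
#'
#' The global maximum and minimum of r with their offsets and (adjusted)
#' p-values. Ties are broken by smaller `|offset|`, then by the more
#' negative offset.
#'
#' @param profile A `positional_profile`.
#' @return A one-row tibble with `motif_id`, `max_offset`, `max_r`,
#'   `max_p`, `max_p_adj`, `min_offset`, `min_r`, `min_p`, `min_p_adj`.
#' @export
profile_extrema <- function(profile) {
  tb <- profile$tbl
  i_max <- order(-tb$r, abs(tb$offset), tb$offset)[1]
  i_min <- order(tb$r, abs(tb$offset), tb$offset)[1]
  tibble(
    motif_id = profile$motif_id,
    max_offset = tb$offset[i_max], max_r = tb$r[i_max],
    max_p = tb$p[i_max], max_p_adj = tb$p_adj[i_max],
    min_offset = tb$offset[i_min], min_r = tb$r[i_min],
    min_p = tb$p[i_min], min_p_adj = tb$p_adj[i_min]
  )
}
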