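# Independent oracles and fixture builders used across the suite. Each
# oracle deliberately takes a different computational route from the
# implementation it checks.

# Exhaustive-enumeration threshold oracle: enumerate all 4^k windows on
# the same integer lattice as the dynamic program and find the smallest
# lattice score whose background tail mass is <= pvalue.
brute_force_threshold <- function(pwm, pvalue, granularity = 0.01) {
  q <- round(pwm$mat / granularity)
  k <- ncol(q)
  stopifnot(k <= 8)
  scores <- 0
  probs <- 1
  for (c in seq_len(k)) {
    scores <- as.vector(outer(scores, q[, c], "+"))
    probs <- as.vector(outer(probs, pwm$background, "*"))
  }
  agg <- rowsum(probs, scores) # probability mass per distinct score
  u <- as.numeric(rownames(agg))
  ord <- order(u)
  u <- u[ord]
  tails <- rev(cumsum(rev(agg[ord, 1])))
  idx <- which(tails <= pvalue + 1e-12)[1]
  if (is.na(idx)) return((max(u) + 1) * granularity)
  u[idx] * granularity
}

# Residual-regression partial correlation oracle.
partial_cor_resid <- function(x, y, z) {
  rx <- stats::resid(stats::lm(x ~ z))
  ry <- stats::resid(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# Hand-written Benjamini-Yekutieli step-up (independent of p.adjust).
by_stepup <- function(p) {
  M <- length(p)
  cM <- sum(1 / seq_len(M))
  ord <- order(p)
  adj_sorted <- pmin(1, M * cM * p[ord] / seq_len(M))
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  out <- numeric(M)
  out[ord] <- adj_sorted
  out
}

# Explicit average-linkage (UPGMA) agglomeration trace over a distance
# matrix, independent of stats::hclust. Returns merge heights in order.
upgma_heights <- function(D) {
  n <- nrow(D)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(active) > 1) {
    m <- length(active)
    best <- c(NA, NA); best_d <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      dij <- mean(D[active[[i]], active[[j]]])
      if (dij < best_d - 1e-12) { best_d <- dij; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- active[-best]
    active[[length(active) + 1]] <- merged
  }
  heights
}

random_motif <- function(k, seed) {
  withr::with_seed(seed, {
    counts <- matrix(stats::rgamma(4 * k, shape = 0.8) * 20, 4, k)
  })
  new_motif_matrix(paste0("RND", seed, "_", k), "random test motif",
                   counts)
}

# small calibrated pwm from a consensus, for hand-traceable scans
consensus_pwm <- function(consensus, pvalue = 1e-3, pseudocount = 1) {
  bases <- strsplit(consensus, "")[[1]]
  counts <- matrix(1, 4, length(bases),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(match(bases, rownames(counts)), seq_along(bases))] <- 50
  calibrate_pwm(build_logodds(new_motif_matrix("CONS", consensus, counts)),
                pvalue = pvalue)
}

random_dna <- function(n, L, seed, probs = rep(0.25, 4)) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
  })
}
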