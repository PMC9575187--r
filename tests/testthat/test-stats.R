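# Positional profile statistics: partial correlation, permutation nulls,
# significance, BY correction, count track and extrema.

make_test_heatmap <- function(seed = 1, n = 60, L = 40, offset = 5) {
  fx <- make_fixture(fixture_preset("strong", seed = seed, n = n,
                                    length = L, offset = offset,
                                    jitter = 1))
  pwm <- calibrate_pwm(build_logodds(fx$spec$motif), pvalue = 1e-3)
  list(fx = fx, hm = build_heatmap(fx$seqs, pwm, margin = 2))
}

test_that("gc_ratio excludes ambiguous bases and flags all-N input", {
  out <- gc_ratio(c("GGCC", "ACGT", "ANGT", "NNNN", "ggcc"))
  expect_equal(as.numeric(out), c(1, 0.5, 1 / 3, 0.5, 1))
  expect_equal(attr(out, "degenerate"), c(FALSE, FALSE, FALSE, TRUE, FALSE))
})

test_that("partial correlation matches the residual-regression oracle", {
  withr::with_seed(99, {
    for (i in 1:40) {
      n <- sample(10:200, 1)
      z <- rnorm(n)
      x <- 0.5 * z + rnorm(n)
      y <- -0.3 * z + 0.4 * x + rnorm(n)
      expect_equal(as.numeric(partial_correlation(x, y, z)),
                   partial_cor_resid(x, y, z), tolerance = 1e-10)
    }
  })
})

test_that("partial correlation degenerate contracts hold", {
  withr::with_seed(4, {
    x <- rnorm(20); y <- rnorm(20); z <- rnorm(20)
  })
  # constant covariate falls back to plain Pearson
  expect_equal(as.numeric(partial_correlation(x, y, rep(2, 20))),
               cor(x, y))
  # constant x or y give flagged zero
  out <- partial_correlation(rep(1, 20), y, z)
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "degenerate"))
  # collinear covariate gives flagged zero
  out2 <- partial_correlation(x, y, x)
  expect_true(attr(out2, "degenerate"))
  expect_error(partial_correlation(1:2, 1:2, 1:2), "n >= 3")
  # near-identity when the covariate is empirically orthogonal
  expect_gt(as.numeric(partial_correlation(x, x, z)), 0.999)
})

test_that("profile recovers a planted offset and respects row alignment", {
  th <- make_test_heatmap(seed = 21)
  r <- positional_profile(th$hm)
  expect_true(all(abs(r) <= 1))
  best <- th$hm$offsets[which.max(r)]
  expect_lte(abs(best - 5), th$hm$margin + th$fx$spec$jitter)

  # all-zero heatmap: everything degenerate
  zero_hm <- th$hm
  zero_hm$smoothed[] <- 0
  r0 <- positional_profile(zero_hm)
  expect_equal(as.numeric(r0), rep(0, length(r0)))
  expect_true(all(attr(r0, "degenerate")))

  # shuffling scores alone changes r; shuffling rows and scores
  # together leaves it unchanged
  withr::with_seed(8, perm <- sample(nrow(th$hm$smoothed)))
  r_shuf <- positional_profile(th$hm, scores = th$hm$scores[perm])
  expect_false(isTRUE(all.equal(as.numeric(r), as.numeric(r_shuf))))
  hm2 <- th$hm
  hm2$smoothed <- th$hm$smoothed[perm, , drop = FALSE]
  r_both <- positional_profile(hm2, scores = th$hm$scores[perm],
                               gc = th$hm$gc[perm])
  expect_equal(as.numeric(r_both), as.numeric(r), tolerance = 1e-12)
})

test_that("negating all scores negates the profile exactly", {
  th <- make_test_heatmap(seed = 33)
  r <- positional_profile(th$hm)
  r_neg <- positional_profile(th$hm, scores = -th$hm$scores)
  expect_equal(as.numeric(r_neg), -as.numeric(r), tolerance = 1e-12)
})

test_that("permutation nulls are seeded and reproducible", {
  th <- make_test_heatmap(seed = 5, n = 40, L = 30)
  n1 <- permutation_null(th$hm, n_perm = 25, seed = 123)
  n2 <- permutation_null(th$hm, n_perm = 25, seed = 123)
  expect_identical(n1, n2)
  n3 <- permutation_null(th$hm, n_perm = 25, seed = 124)
  expect_false(identical(n1, n3))
  expect_equal(dim(n1), c(25, ncol(th$hm$smoothed)))
  expect_true(all(abs(n1) <= 1))
})

test_that("unpermuted scores reproduce the observed profile", {
  th <- make_test_heatmap(seed = 6, n = 40, L = 30)
  eng <- moprof:::profile_engine(th$hm$smoothed, th$hm$gc)
  expect_equal(moprof:::profile_eval(eng, th$hm$scores)$r,
               as.numeric(positional_profile(th$hm)), tolerance = 1e-12)
})

test_that("permutation p-values follow the add-one counting rule", {
  null <- matrix(c(0.1, -0.2, 0.3, -0.4), 4, 1)
  sig <- profile_significance(0.35, null, alpha = 0.05)
  expect_equal(sig$p, (1 + 1) / (4 + 1))
  # observed 0 against a symmetric null: p = 1
  expect_equal(profile_significance(0, null)$p, 1)
  # add-one lower bound
  sig2 <- profile_significance(99, null) # |obs| above all nulls
  expect_equal(sig2$p, 1 / 5)
  expect_true(all(sig$ci_low <= sig$ci_high))
  # normal approximation is monotone in |z|
  sign <- profile_significance(0.35, null, method = "normal")
  expect_lt(sign$p, profile_significance(0.1, null, method = "normal")$p)
})

test_that("BY correction matches an independent step-up to 1e-12", {
  expect_equal(adjust_by(0.03), 0.03)
  p_eq <- rep(0.01, 7)
  expect_equal(adjust_by(p_eq), pmin(1, sum(1 / (1:7)) * p_eq))
  p5 <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  expect_equal(adjust_by(p5), by_stepup(p5), tolerance = 1e-12)
  withr::with_seed(31, {
    for (i in 1:20) {
      p <- runif(sample(5:400, 1))^2
      adj <- adjust_by(p)
      expect_equal(adj, by_stepup(p), tolerance = 1e-12)
      expect_true(all(adj >= p - 1e-15))
      ord <- order(p)
      expect_true(all(diff(adj[ord]) >= -1e-15)) # monotone in raw p
      # invariant to input order
      perm <- sample(length(p))
      expect_equal(adjust_by(p[perm]), adj[perm], tolerance = 1e-12)
    }
  })
  # matrix shape preserved
  m <- matrix(runif(12), 3, 4)
  expect_equal(dim(adjust_by(m)), c(3, 4))
})

test_that("motif count track counts hits and smooths with shrinkage", {
  hm <- list(raw = matrix(0, 5, 9), offsets = -4:4, w = 1L)
  class(hm) <- "motif_heatmap"
  expect_equal(motif_count_track(hm)$count, rep(0L, 9))
  hm$raw[, 5] <- 1 # every row hits at offset 0
  expect_equal(motif_count_track(hm, w = 1)$count[5], 5L)
  tr <- motif_count_track(hm, w = 5)
  expect_equal(tr$count_smoothed[3:7], rep(1, 5)) # 5/5 in the interior
  expect_equal(tr$count_smoothed[2], 0) # window 1..4 misses the spike
  hm$raw[, 5] <- 0
  hm$raw[, 1] <- 1 # spike at the first column
  tre <- motif_count_track(hm, w = 5)
  expect_equal(tre$count_smoothed[1], 5 / 3) # shrunken edge window 1..3
})

test_that("extrema use the |offset| then negative-offset tie rule", {
  mk_prof <- function(r, offsets) {
    structure(list(motif_id = "m",
                   tbl = tibble::tibble(offset = offsets, r = r,
                                        p = 1, p_adj = 1)),
              class = "positional_profile")
  }
  mono <- mk_prof(seq(-1, 1, length.out = 21), -10:10)
  ex <- profile_extrema(mono)
  expect_equal(ex$max_offset, 10)
  expect_equal(ex$min_offset, -10)
  r <- rep(0, 21); r[c(4, 18)] <- 0.9 # offsets -7 and +7
  tie <- profile_extrema(mk_prof(r, -10:10))
  expect_equal(tie$max_offset, -7)
  # planted fixture: max within margin + jitter of the plant
  th <- make_test_heatmap(seed = 55)
  prof <- motif_profile(th$hm, n_perm = 30, seed = 2)
  exf <- profile_extrema(prof)
  expect_lte(abs(exf$max_offset - 5), th$hm$margin + 1)
})

test_that("adjust_profiles corrects across the pooled family", {
  th1 <- make_test_heatmap(seed = 61, n = 40, L = 30)
  th2 <- make_test_heatmap(seed = 62, n = 40, L = 30)
  p1 <- motif_profile(th1$hm, n_perm = 20, seed = 1)
  p2 <- motif_profile(th2$hm, n_perm = 20, seed = 2)
  adj <- adjust_profiles(list(p1, p2))
  pooled <- adjust_by(c(p1$tbl$p, p2$tbl$p))
  expect_equal(adj[[1]]$tbl$p_adj, pooled[seq_len(nrow(p1$tbl))])
  expect_true(all(adj[[2]]$tbl$p_adj >= adj[[2]]$tbl$p - 1e-15))
})
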