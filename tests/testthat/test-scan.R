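# PWM construction, threshold calibration, scanning and smoothing.

test_that("log-odds transform handles symmetry and pseudocounting", {
  uni <- new_motif_matrix("U", "uniform", matrix(1, 4, 3))
  pwm <- build_logodds(uni)
  expect_equal(unname(pwm$mat), matrix(0, 4, 3))

  m <- new_motif_matrix("A4", "a-only", matrix(c(4, 0, 0, 0), 4, 1))
  pwm2 <- build_logodds(m, pseudocount = 1)
  expect_equal(pwm2$mat["A", 1], log2((4.25 / 5) / 0.25),
               ignore_attr = TRUE)
  expect_equal(pwm2$mat["C", 1], log2((0.25 / 5) / 0.25),
               ignore_attr = TRUE)

  # doubling positive counts converges to the same entries as
  # pseudocount -> 0
  pos <- new_motif_matrix("P", "pos", matrix(c(4, 2, 1, 1), 4, 1))
  big <- new_motif_matrix("B", "x", pos$counts * 2)
  p1 <- build_logodds(pos, pseudocount = 1e-9)
  p2 <- build_logodds(big, pseudocount = 1e-9)
  expect_equal(p1$mat, p2$mat, tolerance = 1e-6)
})

test_that("threshold matches hand-worked tail of a single column", {
  m <- new_motif_matrix("S", "single", matrix(c(8, 4, 2, 1), 4, 1))
  pwm <- build_logodds(m)
  # pvalue 1 -> minimum attainable score (every window matches)
  gran <- 0.01
  b_all <- logodds_threshold(pwm, pvalue = 1, granularity = gran)
  expect_equal(b_all, round(min(pwm$mat) / gran) * gran)
  # pvalue 0.25 under uniform background -> only the best base matches
  b <- logodds_threshold(pwm, pvalue = 0.25, granularity = gran)
  expect_equal(b, round(max(pwm$mat) / gran) * gran)
  # pvalue below 0.25 -> nothing can match: one step above the max
  b0 <- logodds_threshold(pwm, pvalue = 0.1, granularity = gran)
  expect_equal(b0, (round(max(pwm$mat) / gran) + 1) * gran)
})

test_that("dynamic-programming threshold equals exhaustive enumeration", {
  for (seed in 1:8) {
    k <- 1 + (seed %% 8)
    motif <- random_motif(k, seed + 100)
    bg <- if (seed %% 2) rep(0.25, 4) else c(0.3, 0.2, 0.2, 0.3)
    pwm <- build_logodds(motif, background = bg)
    for (pv in c(1, 0.05, 1e-3)) {
      expect_equal(logodds_threshold(pwm, pv, 0.01),
                   brute_force_threshold(pwm, pv, 0.01),
                   info = sprintf("seed %d pv %g", seed, pv))
    }
  }
})

test_that("scan_row masks non-ACGT windows and pads to length L", {
  pwm <- consensus_pwm("ACG")
  expect_equal(scan_row(strrep("N", 12), pwm), rep(0, 12))
  for (L in c(3, 5, 10)) {
    expect_length(scan_row(strrep("A", L), pwm), L)
  }
  expect_warning(out <- scan_row("AC", pwm), "shorter")
  expect_equal(out, c(0, 0))
})

test_that("single-base motif scan at pvalue 1 traces by hand", {
  m <- new_motif_matrix("A1", "a", matrix(c(10, 0, 0, 0), 4, 1))
  pwm <- calibrate_pwm(build_logodds(m), pvalue = 1)
  # b = min column score (the non-A entries); A scores exceed b
  row <- scan_row("ACGT", pwm)
  expected <- pmax(pwm$mat[c("A", "C", "G", "T"), 1] - pwm$threshold, 0)
  expect_equal(row, unname(expected))
  expect_true(row[1] > 0)
  expect_true(all(row[1] > row[2:4])) # the preferred base scores highest
})

test_that("both-strand scan is a positionwise max and an involution", {
  pwm <- consensus_pwm("ACGTT", pvalue = 0.016)
  seq <- "TTACGTTGGAACGTT"
  fwd <- scan_row(seq, pwm)
  rc <- rev(scan_row(revcomp(seq), pwm))
  expect_equal(scan_row_both(seq, pwm), pmax(fwd, rc))
  expect_true(any(rev(scan_row(revcomp(seq), pwm)) > 0))

  # palindromic matrix: both-strand equals forward
  pal_counts <- matrix(c(10, 1, 1, 10), 4, 2,
                       dimnames = list(c("A", "C", "G", "T"), NULL))
  # columns (A-heavy, T-heavy): revcomp of the matrix equals itself
  pal <- calibrate_pwm(build_logodds(
    new_motif_matrix("PAL", "at", pal_counts)), pvalue = 0.2)
  s <- "GGATCCATTA"
  expect_equal(scan_row_both(s, pal), scan_row(s, pal))

  # involution on fuzzed sequences
  pwm2 <- consensus_pwm("GATAAG", pvalue = 0.05)
  for (s in random_dna(5, 40, seed = 77)) {
    expect_equal(scan_row_both(s, pwm2),
                 rev(scan_row_both(revcomp(s), pwm2)))
  }
})

test_that("motif-center placement follows the floor((k-1)/2) convention", {
  # width-3 consensus planted at a known window start
  # pvalue chosen so the threshold sits strictly below the consensus
  # score (a window scoring exactly b has zero excess by definition)
  pwm <- consensus_pwm("GCG", pvalue = 0.16)
  s <- paste0(strrep("A", 4), "GCG", strrep("A", 5)) # start 5 (1-based)
  row <- scan_row(s, pwm)
  expect_equal(which(row > 0), 5L + 1L) # s + floor((k-1)/2) = 5 + 1
  # even width: center sits left of middle
  pwm2 <- consensus_pwm("GCGC", pvalue = 0.051)
  s2 <- paste0(strrep("A", 4), "GCGC", strrep("A", 4))
  expect_equal(which(scan_row(s2, pwm2) > 0), 5L + 1L)
})

test_that("average-pool smoothing obeys kernel arithmetic", {
  raw <- matrix(0, 2, 11)
  raw[1, 6] <- 10
  expect_identical(smooth_heatmap(raw, 0), raw)
  sm <- smooth_heatmap(raw, 2)
  expect_equal(sm[1, 4:8], rep(2, 5))
  expect_equal(sum(sm[1, ]), 10)
  # spike at the first column leaks mass off the edge: 2v/3 remains
  edge <- matrix(c(9, rep(0, 8)), 1, 9)
  expect_equal(sum(smooth_heatmap(edge, 1)), 2 * 9 / 3)
  # smoothing commutes with row permutation
  withr::with_seed(3, M <- matrix(stats::rexp(60), 6, 10))
  perm <- c(4, 1, 6, 2, 3, 5)
  expect_equal(smooth_heatmap(M, 2)[perm, ], smooth_heatmap(M[perm, ], 2))
})

test_that("heatmaps are non-negative, sorted by score, zero where padded", {
  fx <- make_fixture(fixture_preset("strong", seed = 42, n = 100,
                                    length = 80, offset = 10))
  pwm <- calibrate_pwm(build_logodds(fx$spec$motif), pvalue = 1e-4)
  hm <- build_heatmap(fx$seqs, pwm, margin = 2)
  expect_true(all(hm$raw >= 0))
  expect_true(all(hm$smoothed >= 0))
  expect_equal(hm$scores, sort(fx$seqs$score, decreasing = TRUE))
  k <- ncol(pwm$mat)
  L <- ncol(hm$raw)
  expect_equal(hm$raw[, seq_len((k - 1L) %/% 2L)],
               matrix(0, nrow(hm$raw), (k - 1L) %/% 2L))
  # hits concentrate at the planted offset +/- jitter
  hit_cols <- which(colSums(hm$raw > 0) > 0)
  hit_offsets <- hm$offsets[hit_cols]
  expect_true(all(abs(hit_offsets - 10) <= fx$spec$jitter))
  expect_true(length(hit_cols) >= 1)
  # stable tie-breaking: equal scores keep input order
  ties <- tibble::tibble(id = c("x", "y", "z"),
                         seq = c("ACGT", "GGGG", "TTTT"),
                         score = c(1, 1, 2))
  hm2 <- build_heatmap(ties, consensus_pwm("AC"), margin = 0)
  expect_equal(hm2$ids, c("z", "x", "y"))
})

test_that("empirical background match rate agrees with the lattice tail", {
  motif <- random_motif(6, 314)
  gran <- 0.01
  pv <- 0.01
  pwm <- calibrate_pwm(build_logodds(motif), pvalue = pv,
                       granularity = gran)
  # lattice-rounded twin of the same PWM: raw > 0 then corresponds
  # exactly to lattice score >= threshold
  lat <- pwm
  lat$mat <- round(pwm$mat / gran) * gran
  lat$threshold <- pwm$threshold - 1e-9
  n <- 2000
  L <- 105 # 100 windows per sequence
  seqs <- tibble::tibble(id = as.character(seq_len(n)),
                         seq = random_dna(n, L, seed = 271),
                         score = 0)
  hm <- build_heatmap(seqs, lat, margin = 0, orientation = "forward")
  W <- L - ncol(pwm$mat) + 1
  rate <- sum(hm$raw > 0) / (n * W)
  # exact tail mass at the calibrated threshold from enumeration
  q <- round(pwm$mat / gran)
  scores <- 0; probs <- 1
  for (c in seq_len(ncol(q))) {
    scores <- as.vector(outer(scores, q[, c], "+"))
    probs <- as.vector(outer(probs, pwm$background, "*"))
  }
  tail_mass <- sum(probs[scores * gran >= pwm$threshold - 1e-9])
  expect_lte(tail_mass, pv + 1e-12)
  sd3 <- 3 * sqrt(tail_mass * (1 - tail_mass) / (n * W))
  expect_lt(abs(rate - tail_mass), sd3 + 1e-12)
  expect_lte(rate, pv + sd3)
})
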