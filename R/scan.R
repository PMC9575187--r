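# Log-odds PWMs, p-value calibrated match thresholds, and heatmap scanning.
#
# A motif's match strength at a window is the summed log2-odds of the
# window under the pseudocounted PWM versus the background. The match
# threshold b is calibrated so that the probability of a window scoring
# >= b under i.i.d. background draws is at most a target p-value; the
# exact background score distribution is computed by dynamic-programming
# convolution on a discretized score lattice.

#' Build a log-odds PWM from a motif count matrix
#'
#' Counts are pseudocounted proportionally to the background
#' (`counts + pseudocount * background` per base), converted to column
#' probabilities, and log2-transformed against the background. A uniform
#' count column under a uniform background therefore scores exactly 0.
#'
#' @param motif A `motif_matrix`.
#' @param background Length-4 base probabilities (A, C, G, T), strictly
#'   positive, summing to 1. Default uniform.
#' @param pseudocount Positive pseudocount mass per column (default 1).
#' @return A `logodds_pwm` object (no threshold yet; see
#'   [logodds_threshold()] / [calibrate_pwm()]).
#' @export
build_logodds <- function(motif, background = rep(0.25, 4),
                          pseudocount = 1) {
  stopifnot(inherits(motif, "motif_matrix"),
            length(background) == 4L, all(background > 0),
            abs(sum(background) - 1) < 1e-8, pseudocount > 0)
  counts <- motif$counts
  padded <- counts + pseudocount * background
  probs <- sweep(padded, 2, colSums(padded), "/")
  mat <- log2(probs / background)
  dimnames(mat) <- dimnames(counts)
  structure(list(id = motif$id, name = motif$name, mat = mat,
                 background = background, pseudocount = pseudocount,
                 threshold = NULL, pvalue = NULL, granularity = NULL),
            class = "logodds_pwm")
}

#' @export
print.logodds_pwm <- function(x, ...) {
  cat("<logodds_pwm> ", x$id, ", width ", ncol(x$mat), sep = "")
  if (!is.null(x$threshold)) {
    cat(sprintf(", threshold %.3f bits (p <= %g)", x$threshold, x$pvalue))
  }
  cat("\n")
  invisible(x)
}

#' Log-odds match threshold at a background p-value
#'
#' Discretizes the PWM entries to an integer lattice with step
#' `granularity` (in bits) and builds the exact distribution of window
#' scores under i.i.d. background draws by convolving the per-column
#' score distributions. The threshold is the smallest lattice score `t`
#' with tail mass `P(score >= t) <= pvalue`, mapped back to bits. If even
#' the maximal score has tail mass above `pvalue`, the threshold is one
#' lattice step above the maximum (no window matches).
#'
#' @param pwm A `logodds_pwm`.
#' @param pvalue Target match p-value in `(0, 1]`.
#' @param granularity Lattice step in bits (default 0.01).
#' @param max_lattice Maximum lattice span before erroring with advice to
#'   coarsen the granularity.
#' @return The threshold (numeric scalar, bits).
#' @export
logodds_threshold <- function(pwm, pvalue = 1e-4, granularity = 0.01,
                              max_lattice = 1e7) {
  stopifnot(inherits(pwm, "logodds_pwm"),
            pvalue > 0, pvalue <= 1, granularity > 0)
  q <- round(pwm$mat / granularity)
  k <- ncol(q)
  lo <- sum(apply(q, 2, min))
  hi <- sum(apply(q, 2, max))
  if (hi - lo + 1 > max_lattice) {
    abort(paste0("score lattice too large (", hi - lo + 1,
                 " cells); increase `granularity`"))
  }
  dist <- 1 # P(score offset = 0), offset relative to running lower bound
  run_lo <- 0
  bg <- pwm$background
  for (c in seq_len(k)) {
    v <- q[, c]
    new_lo <- run_lo + min(v)
    new_hi <- run_lo + length(dist) - 1 + max(v)
    new <- numeric(new_hi - new_lo + 1)
    for (b in 1:4) {
      at <- (run_lo + v[b]) - new_lo # 0-based shift into `new`
      idx <- seq_along(dist) + at
      new[idx] <- new[idx] + dist * bg[b]
    }
    dist <- new
    run_lo <- new_lo
  }
  tail <- rev(cumsum(rev(dist))) # tail[i] = P(score >= lo + i - 1)
  # threshold must be an achievable score: skip zero-probability cells
  ok <- which(tail <= pvalue + 1e-12 & dist > 0)
  if (length(ok) == 0L) {
    return((hi + 1) * granularity)
  }
  (lo + ok[1] - 1) * granularity
}

#' Attach a calibrated match threshold to a PWM
#'
#' @inheritParams logodds_threshold
#' @return The `logodds_pwm` with `threshold`, `pvalue` and `granularity`
#'   fields set.
#' @export
calibrate_pwm <- function(pwm, pvalue = 1e-4, granularity = 0.01,
                          max_lattice = 1e7) {
  pwm$threshold <- logodds_threshold(pwm, pvalue, granularity, max_lattice)
  pwm$pvalue <- pvalue
  pwm$granularity <- granularity
  pwm
}

# Scan an encoded base matrix (n x L, codes 1..5) with a calibrated PWM on
# the forward strand. Returns the n x L matrix of clipped threshold
# excesses max(0, score - b), with motif-center placement and zero padding.
scan_encoded <- function(enc, pwm) {
  stopifnot(!is.null(pwm$threshold))
  n <- nrow(enc)
  L <- ncol(enc)
  k <- ncol(pwm$mat)
  out <- matrix(0, n, L)
  if (L < k) {
    warn(paste0("sequences shorter than motif ", pwm$id, "; all-zero scan"))
    return(out)
  }
  W <- L - k + 1L
  lut <- rbind(pwm$mat, -Inf) # row 5: windows over non-ACGT never match
  scores <- matrix(0, n, W)
  for (c in seq_len(k)) {
    block <- enc[, c:(c + W - 1L), drop = FALSE]
    scores <- scores + matrix(lut[cbind(as.vector(block), c)], n, W)
  }
  hits <- pmax(scores - pwm$threshold, 0)
  out[, seq_len(W) + (k - 1L) %/% 2L] <- hits
  out
}

#' Scan one sequence with a motif on the forward strand
#'
#' Each window of width k starting at position s contributes
#' `max(0, score - b)` at the motif-center index `s + floor((k - 1) / 2)`;
#' positions where no full window maps, and windows overlapping non-ACGT
#' bases, are 0.
#'
#' @param seq A DNA string (length L >= motif width; case-insensitive,
#'   `N`/other bases mask their windows).
#' @param pwm A calibrated `logodds_pwm` (see [calibrate_pwm()]).
#' @return A non-negative numeric vector of length `nchar(seq)`.
#' @export
scan_row <- function(seq, pwm) {
  as.numeric(scan_encoded(encode_seqs(seq), pwm))
}

#' Scan one sequence with a motif on both strands
#'
#' The positionwise maximum of the forward scan and the reversed scan of
#' the reverse complement, so a match on either strand registers at the
#' same displayed position.
#'
#' @inheritParams scan_row
#' @return A non-negative numeric vector of length `nchar(seq)`.
#' @export
scan_row_both <- function(seq, pwm) {
  enc <- encode_seqs(seq)
  fwd <- scan_encoded(enc, pwm)
  rc <- scan_encoded(revcomp_encoded(enc), pwm)
  as.numeric(pmax(fwd, rc[, rev(seq_len(ncol(rc))), drop = FALSE]))
}

#' Average-pool smoothing of heatmap rows
#'
#' Convolves every row with a uniform kernel of width `w = 1 + 2 * margin`
#' at stride 1, zero-padded so the output width equals the input width.
#' `margin = 0` is the identity.
#'
#' @param raw Numeric matrix (sequences x positions).
#' @param margin Non-negative integer motif margin m.
#' @return A matrix of the same dimensions.
#' @export
smooth_heatmap <- function(raw, margin) {
  stopifnot(margin >= 0)
  if (margin == 0) return(raw)
  w <- 1 + 2 * margin
  acc <- raw
  for (d in seq_len(margin)) {
    acc <- acc + shift_cols(raw, d) + shift_cols(raw, -d)
  }
  acc / w
}

#' Build a motif score heatmap for a scored sequence set
#'
#' Scans every sequence with the calibrated PWM, orders rows by descending
#' sequence score (stable in input order for ties), and attaches the
#' smoothed matrix and the position axis. Offsets measure the displacement
#' of the motif center from the sequence center (index `floor(L / 2)`,
#' 0-based).
#'
#' @param x Scored sequence tibble (`id`, `seq`, `score`).
#' @param pwm A calibrated `logodds_pwm`.
#' @param margin Motif margin m; the pooling window is `w = 1 + 2 * m`.
#'   Use ~2 bp for single-nucleotide anchors (TSS), larger (e.g. 10 bp)
#'   for imprecise anchors such as peak summits.
#' @param orientation `"both"` (default) scans both strands, `"forward"`
#'   only the given strand.
#' @return A `motif_heatmap` object: list with `motif_id`, `raw`,
#'   `smoothed` (n x L matrices, rows in descending score order),
#'   `offsets`, `margin`, `w`, `orientation`, plus the aligned `ids`,
#'   `scores` and `gc` vectors.
#' @export
build_heatmap <- function(x, pwm, margin = 2,
                          orientation = c("both", "forward")) {
  orientation <- match.arg(orientation)
  validate_scored_seqs(x)
  ord <- order(-x$score)
  x <- x[ord, , drop = FALSE]
  enc <- encode_seqs(x$seq)
  raw <- scan_encoded(enc, pwm)
  if (orientation == "both") {
    rc <- scan_encoded(revcomp_encoded(enc), pwm)
    raw <- pmax(raw, rc[, rev(seq_len(ncol(rc))), drop = FALSE])
  }
  L <- ncol(enc)
  structure(list(
    motif_id = pwm$id,
    raw = raw,
    smoothed = smooth_heatmap(raw, margin),
    offsets = seq_len(L) - (L %/% 2L + 1L),
    margin = margin,
    w = 1L + 2L * as.integer(margin),
    orientation = orientation,
    ids = x$id,
    scores = x$score,
    gc = gc_ratio(x$seq)
  ), class = "motif_heatmap")
}

#' @export
print.motif_heatmap <- function(x, ...) {
  cat("<motif_heatmap> ", x$motif_id, ": ", nrow(x$raw), " sequences x ",
      ncol(x$raw), " positions, margin ", x$margin,
      ", orientation ", x$orientation, "\n", sep = "")
  invisible(x)
}

#' Export a heatmap matrix as a tab-separated table
#'
#' One row per sequence (descending score order), one column per offset.
#'
#' @param hm A `motif_heatmap`.
#' @param path Output path.
#' @param which `"smoothed"` (default) or `"raw"`.
#' @return The path, invisibly.
#' @export
write_heatmap_tsv <- function(hm, path, which = c("smoothed", "raw")) {
  which <- match.arg(which)
  M <- hm[[which]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", hm$offsets), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(M)), function(i) {
    paste(c(hm$ids[i], fmt_num(M[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}
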