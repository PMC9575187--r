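# Shared low-level helpers: sequence encoding, reverse complement, seeding.

# byte -> base code lookup: A/a=1, C/c=2, G/g=3, T/t=4, anything else 5
.base_code <- local({
  lut <- rep(5L, 256L)
  lut[utf8ToInt("A") + 1L] <- 1L; lut[utf8ToInt("a") + 1L] <- 1L
  lut[utf8ToInt("C") + 1L] <- 2L; lut[utf8ToInt("c") + 1L] <- 2L
  lut[utf8ToInt("G") + 1L] <- 3L; lut[utf8ToInt("g") + 1L] <- 3L
  lut[utf8ToInt("T") + 1L] <- 4L; lut[utf8ToInt("t") + 1L] <- 4L
  lut
})

# complement of the integer code (N and unknowns stay 5)
.comp_code <- c(4L, 3L, 2L, 1L, 5L)

#' Reverse complement of DNA strings, preserving case
#'
#' Complements A/C/G/T (upper or lower case) and reverses each string.
#' Soft-masking (lowercase) is preserved; any other character maps to `N`
#' (or `n` if lowercase).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("AACGtt")
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTacgtUuRYKMBDHVrykmbdhv",
                 "TGCAtgcaAaNNNNNNNNnnnnnnnn", x)
  vapply(comp, function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Encode a character vector of equal-length sequences as an n x L integer
# matrix of base codes (1..4 = ACGT, 5 = other/N).
encode_seqs <- function(seqs) {
  n <- length(seqs)
  if (n == 0L) return(matrix(integer(0), 0L, 0L))
  L <- nchar(seqs[[1L]])
  stopifnot(all(nchar(seqs) == L))
  codes <- .base_code[utf8ToInt(paste(seqs, collapse = "")) + 1L]
  matrix(codes, nrow = n, ncol = L, byrow = TRUE)
}

# Reverse-complement an encoded matrix (reverse columns, complement codes).
revcomp_encoded <- function(enc) {
  out <- matrix(.comp_code[enc], nrow = nrow(enc), ncol = ncol(enc))
  out[, rev(seq_len(ncol(out))), drop = FALSE]
}

#' Derive a reproducible per-motif seed from a global seed and an identifier
#'
#' Per-motif random streams are keyed on `(seed, id)` so that serial and
#' parallel executions of the pipeline produce identical results regardless
#' of worker count.
#'
#' @param seed Integer global seed.
#' @param id Character identifier (e.g. a motif ID).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, id) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(id) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (ch in utf8ToInt(as.character(id))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

# shift matrix columns by d (positive = right), zero padding
shift_cols <- function(M, d) {
  L <- ncol(M)
  out <- matrix(0, nrow(M), L)
  if (d >= 0) {
    if (d < L) out[, (1L + d):L] <- M[, 1L:(L - d), drop = FALSE]
  } else {
    if (-d < L) out[, 1L:(L + d)] <- M[, (1L - d):L, drop = FALSE]
  }
  out
}

# centered rolling mean with edge shrinkage (window shrinks at the borders)
rolling_mean <- function(x, w) {
  stopifnot(w >= 1L)
  if (w == 1L) return(as.numeric(x))
  m <- (w - 1L) %/% 2L
  L <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(L) - m, 1L)
  hi <- pmin(seq_len(L) + m, L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# fixed numeric formatting shared by TSV and HTML output so the two are
# byte-consistent and reruns are deterministic
fmt_num <- function(x) {
  out <- sprintf("%.6g", x)
  out[is.na(x)] <- "NA"
  out
}

stop_input <- function(msg) {
  abort(msg, class = "moprof_input_error")
}
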