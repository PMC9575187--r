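# broom-style tidiers for fitted objects.

#' Tidy a positional profile
#'
#' @param x A `positional_profile`.
#' @param ... Unused.
#' @return A tibble with one row per offset (`motif_id`, `offset`, `r`,
#'   `degenerate`, `ci_low`, `ci_high`, `null_mean`, `null_sd`, `p`,
#'   `p_adj`, `count`, `count_smoothed`).
#' @method tidy positional_profile
#' @export
tidy.positional_profile <- function(x, ...) {
  dplyr::bind_cols(tibble(motif_id = x$motif_id), x$tbl)
}

#' One-row summary of a positional profile
#'
#' @param x A `positional_profile`.
#' @param ... Unused.
#' @return The [profile_extrema()] row plus `n_perm` and `seed`.
#' @method glance positional_profile
#' @export
glance.positional_profile <- function(x, ...) {
  dplyr::bind_cols(profile_extrema(x),
                   tibble(n_perm = x$n_perm, seed = x$seed))
}

#' Tidy a pipeline result
#'
#' @param x A `moprof_result`.
#' @param ... Unused.
#' @return Per-offset rows for all motifs, bound together.
#' @method tidy moprof_result
#' @export
tidy.moprof_result <- function(x, ...) {
  dplyr::bind_rows(lapply(x$profiles, tidy.positional_profile))
}

#' One-row summary of a pipeline result
#'
#' Per-motif extrema live in `x$extrema`; this is the single-row run
#' summary in the broom sense.
#'
#' @param x A `moprof_result`.
#' @param ... Unused.
#' @return A one-row tibble (`n_motifs`, `n_sequences`, `length`,
#'   `n_perm`, `seed`, `best_motif`, `best_r`, `best_offset`,
#'   `min_p_adj`).
#' @method glance moprof_result
#' @export
glance.moprof_result <- function(x, ...) {
  best <- which.max(abs(c(x$extrema$max_r, x$extrema$min_r)))
  m <- nrow(x$extrema)
  use_max <- best <= m
  i <- if (use_max) best else best - m
  tibble(
    n_motifs = m,
    n_sequences = x$config$n_sequences,
    length = x$config$length,
    n_perm = x$config$n_perm,
    seed = x$config$seed,
    best_motif = x$extrema$motif_id[i],
    best_r = if (use_max) x$extrema$max_r[i] else x$extrema$min_r[i],
    best_offset = if (use_max) x$extrema$max_offset[i] else
      x$extrema$min_offset[i],
    min_p_adj = min(x$extrema$max_p_adj, x$extrema$min_p_adj))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
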