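# End-to-end orchestration: read inputs, filter, scan every motif,
# compute profiles and significance, correct across the whole motif set,
# cluster, and render reports. Per-motif permutation streams are keyed on
# (seed, motif_id) so results are identical for any worker count.

#' Run the full positional motif enrichment pipeline
#'
#' @param seqs A scored sequence tibble, or a path to a scored FASTA
#'   file.
#' @param motifs A named list of `motif_matrix` objects, or a path to a
#'   JASPAR PFM file.
#' @param out_dir Output directory (created if needed). `NULL` skips all
#'   file output and returns the result object only.
#' @param margin Motif margin m; smoothing window `w = 1 + 2m`. Use ~2 bp
#'   for single-base anchors, ~10 bp for peak summits.
#' @param match_pvalue Background p-value for the motif match threshold.
#' @param pseudocount PWM pseudocount.
#' @param background `"uniform"` (default) or `"empirical"`
#'   (mono-nucleotide frequencies estimated from the input sequences), or
#'   a length-4 numeric probability vector (A, C, G, T).
#' @param orientation `"both"` or `"forward"`.
#' @param n_perm Number of score permutations per motif.
#' @param seed Global seed; each motif's stream derives from
#'   `(seed, motif_id)`.
#' @param alpha Confidence-band level (default 0.05).
#' @param granularity Threshold lattice step in bits.
#' @param max_masked_frac Masked-fraction filter threshold, see
#'   [filter_sequences()].
#' @param dedupe Deduplicate overlapping intervals before analysis?
#' @param jobs Number of parallel workers for per-motif work.
#' @param figures Render per-motif figures? (Figure rendering dominates
#'   runtime for small inputs.)
#' @return A `moprof_result`: list with `profiles` (named list of
#'   `positional_profile`), `heatmaps`, `extrema` (tibble), `clustering`,
#'   `files` (paths written) and `config`.
#' @export
run_profiling <- function(seqs, motifs, out_dir = NULL,
                          margin = 2, match_pvalue = 1e-4,
                          pseudocount = 1, background = "uniform",
                          orientation = c("both", "forward"),
                          n_perm = 1000, seed = 1, alpha = 0.05,
                          granularity = 0.01, max_masked_frac = 0.5,
                          dedupe = FALSE, jobs = 1, figures = TRUE) {
  orientation <- match.arg(orientation)
  if (is.character(seqs) && length(seqs) == 1L) {
    seqs <- read_scored_fasta(seqs)
  }
  validate_scored_seqs(seqs)
  if (is.character(motifs) && length(motifs) == 1L) {
    motifs <- read_jaspar(motifs)
  }
  stopifnot(length(motifs) >= 1)
  n_before <- nrow(seqs)
  seqs <- filter_sequences(seqs, max_masked_frac, dedupe)
  if (nrow(seqs) == 0L) {
    abort("no sequences left after filtering", class = "moprof_empty_error")
  }
  message(sprintf("kept %d / %d sequences after filtering",
                  nrow(seqs), n_before))

  bg <- resolve_background(background, seqs$seq)
  config <- list(
    n_sequences = nrow(seqs), n_input_sequences = n_before,
    length = nchar(seqs$seq[[1]]), margin = margin,
    match_pvalue = match_pvalue, pseudocount = pseudocount,
    background = bg, orientation = orientation, n_perm = n_perm,
    seed = seed, alpha = alpha, granularity = granularity,
    max_masked_frac = max_masked_frac, dedupe = dedupe, jobs = jobs,
    version = as.character(packageVersion("moprof")))

  one_motif <- function(motif) {
    pwm <- calibrate_pwm(build_logodds(motif, bg, pseudocount),
                         match_pvalue, granularity)
    hm <- build_heatmap(seqs, pwm, margin, orientation)
    prof <- motif_profile(hm, n_perm = n_perm,
                          seed = derive_seed(seed, motif$id),
                          alpha = alpha)
    list(heatmap = hm, profile = prof)
  }
  results <- if (jobs > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(motifs, one_motif, mc.cores = jobs)
  } else {
    lapply(motifs, one_motif)
  }
  heatmaps <- lapply(results, `[[`, "heatmap")
  profiles <- adjust_profiles(lapply(results, `[[`, "profile"))
  names(profiles) <- names(heatmaps) <- vapply(motifs, `[[`,
                                               character(1), "id")
  extrema <- dplyr::bind_rows(lapply(profiles, profile_extrema))
  clustering <- cluster_profiles(profiles)

  files <- list()
  if (!is.null(out_dir)) {
    files <- write_outputs(out_dir, motifs, heatmaps, profiles, extrema,
                           clustering, config, figures)
  }
  structure(list(profiles = profiles, heatmaps = heatmaps,
                 extrema = extrema, clustering = clustering,
                 files = files, config = config),
            class = "moprof_result")
}

resolve_background <- function(background, seqs) {
  if (is.numeric(background)) {
    stopifnot(length(background) == 4L, all(background > 0))
    return(background / sum(background))
  }
  if (identical(background, "uniform")) return(rep(0.25, 4))
  if (identical(background, "empirical")) {
    enc <- encode_seqs(seqs)
    tab <- tabulate(enc[enc <= 4L], nbins = 4L)
    if (sum(tab) == 0L) return(rep(0.25, 4))
    return(pmax(tab, 1) / sum(pmax(tab, 1)))
  }
  stop_input("background must be 'uniform', 'empirical' or 4 probabilities")
}

write_outputs <- function(out_dir, motifs, heatmaps, profiles, extrema,
                          clustering, config, figures) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "profiles"), showWarnings = FALSE)
  files <- list(profiles = character(0), figures = character(0))
  ids <- names(profiles)
  safe <- gsub("[^A-Za-z0-9._-]", "_", ids)
  fig_rel <- NULL
  if (figures) {
    dir.create(file.path(out_dir, "figures"), showWarnings = FALSE)
    fig_rel <- stats::setNames(file.path("figures",
                                         paste0(safe, ".png")), ids)
  }
  for (i in seq_along(ids)) {
    id <- ids[i]
    p <- file.path(out_dir, "profiles", paste0(safe[i], ".tsv"))
    write_profile_tsv(profiles[[id]], p)
    files$profiles <- c(files$profiles, p)
    if (figures) {
      fp <- render_motif_figure(heatmaps[[id]], profiles[[id]],
                                motifs[[id]],
                                file.path(out_dir, fig_rel[[id]]))
      files$figures <- c(files$figures, fp)
      fig_rel[[id]] <- file.path("figures", basename(fp))
    }
  }
  files$extrema <- file.path(out_dir, "extrema.tsv")
  write_extrema_tsv(extrema, files$extrema)
  files$table <- file.path(out_dir, "results_table.html")
  render_results_table(extrema, profiles, motifs, files$table, fig_rel)
  files$clustermap <- file.path(out_dir, "clustermap.html")
  render_clustermap(clustering, profiles, files$clustermap, fig_rel)
  files$manifest <- file.path(out_dir, "manifest.json")
  rel <- function(x) sub(paste0("^", out_dir, "/?"), "", x)
  manifest <- list(parameters = config,
                   files = lapply(files[names(files) != "manifest"],
                                  function(f) unname(rel(f))))
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files
}

#' @export
print.moprof_result <- function(x, ...) {
  cat("<moprof_result> ", length(x$profiles), " motifs x ",
      x$config$n_sequences, " sequences (L = ", x$config$length,
      " bp, seed ", x$config$seed, ")\n", sep = "")
  print(x$extrema)
  invisible(x)
}
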