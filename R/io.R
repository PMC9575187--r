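# Reading and writing scored sequence sets and motif libraries.
#
# The scored FASTA format is ordinary FASTA whose header line carries the
# sequence score as its final whitespace-separated numeric token:
#   >peak_1 chr1:100-500 -1.25
#   ACGT...
# Everything on the header before the score token is the sequence ID.

#' Read a scored FASTA file
#'
#' Parses a FASTA file in which each header line ends with a numeric
#' sequence score, separated from the ID by whitespace. The score is taken
#' as the last whitespace-separated header token that parses as a number;
#' the text before it (which may itself contain spaces) is the ID.
#' Sequences may span multiple lines; case is preserved so that
#' soft-masking survives into downstream filtering. Gzipped input is
#' handled transparently.
#'
#' @param path Path to the scored FASTA file.
#' @return A tibble with columns `id` (character), `seq` (character,
#'   uniform length) and `score` (numeric).
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">seq1 2.5", "ACGT", ">seq2 -1", "GGCC"), f)
#' read_scored_fasta(f)
read_scored_fasta <- function(path) {
  if (!file.exists(path)) stop_input(paste0("file not found: ", path))
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  seqs <- as.character(ss)
  parsed <- parse_scored_headers(headers, path)
  out <- tibble(id = parsed$id, seq = unname(seqs), score = parsed$score)
  check_uniform_length(out)
  out
}

# Split headers into (id, score) by the last float-parsable token.
parse_scored_headers <- function(headers, path = "<input>") {
  n <- length(headers)
  ids <- character(n)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    h <- headers[[i]]
    toks <- regmatches(h, gregexpr("\\S+", h))[[1]]
    starts <- gregexpr("\\S+", h)[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    ok <- which(!is.na(vals))
    if (length(ok) == 0L) {
      line <- scored_header_line(path, h)
      stop_input(sprintf(
        "no numeric score token in header '%s'%s", h,
        if (is.na(line)) "" else sprintf(" (line %d)", line)))
    }
    j <- max(ok)
    scores[i] <- vals[j]
    ids[i] <- trimws(substr(h, 1L, starts[j] - 1L))
  }
  if (any(!is.finite(scores))) {
    stop_input("non-finite sequence scores are not allowed")
  }
  list(id = ids, score = scores)
}

# best-effort line number of a header for error messages
scored_header_line <- function(path, header) {
  if (!file.exists(path)) return(NA_integer_)
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) NULL)
  if (is.null(lines)) return(NA_integer_)
  hit <- which(lines == paste0(">", header))
  if (length(hit)) hit[1] else NA_integer_
}

check_uniform_length <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  L <- nchar(x$seq[[1]])
  bad <- which(nchar(x$seq) != L)
  if (length(bad)) {
    stop_input(paste0(
      "sequences differ in length (expected ", L, " bp): ",
      paste(x$id[bad], collapse = ", ")))
  }
  invisible(x)
}

#' Write a scored FASTA file
#'
#' Inverse of [read_scored_fasta()]: writes each record as
#' `>id score` followed by the sequence on one line. Scores are written
#' with 17 significant digits so that read/write round-trips are exact.
#'
#' @param x Tibble with columns `id`, `seq`, `score`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_scored_fasta <- function(x, path) {
  validate_scored_seqs(x)
  lines <- character(0)
  if (nrow(x) > 0L) {
    lines <- as.vector(rbind(
      paste0(">", x$id, " ", sprintf("%.17g", x$score)),
      x$seq))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# Minimal structural validation for a scored sequence set.
validate_scored_seqs <- function(x) {
  if (!is.data.frame(x) || !all(c("id", "seq", "score") %in% names(x))) {
    stop_input("expected a data frame with columns id, seq, score")
  }
  if (any(!is.finite(x$score))) stop_input("scores must be finite")
  check_uniform_length(x)
  invisible(x)
}

#' Read a BED6 file of scored intervals
#'
#' @param path Path to a tab-separated BED file with at least 6 columns:
#'   chrom, start (0-based), end (exclusive), name, score, strand.
#' @return A tibble with those six columns; `'.'` strands are kept as-is
#'   (they are treated as `'+'` at extraction time).
#' @export
read_bed6 <- function(path) {
  if (!file.exists(path)) stop_input(paste0("file not found: ", path))
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = c("character", "integer", "integer",
                                  "character", "numeric", "character"),
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand"),
                   comment.char = "#", quote = "")
  if (any(df$start >= df$end)) stop_input("BED intervals must have start < end")
  as_tibble(df)
}

#' Extract scored sequences from a BED file and a reference genome
#'
#' Converts a set of equal-width scored genomic intervals into a scored
#' sequence set by extracting `[start, end)` from the genome (0-based
#' half-open), reverse-complementing minus-strand intervals. The BED score
#' column becomes the sequence score. Genome case is preserved so that
#' soft-masked (lowercase) bases can drive repeat filtering downstream.
#'
#' @param bed A tibble as returned by [read_bed6()], or a path to a BED6
#'   file.
#' @param genome A named character vector of chromosome sequences, or a
#'   path to a genome FASTA file.
#' @return A tibble with columns `id`, `seq`, `score`, `chrom`, `start`,
#'   `end`, `strand`. Records that fall off a chromosome end or name a
#'   missing chromosome are dropped with a warning.
#' @export
get_scored_fasta <- function(bed, genome) {
  if (is.character(bed) && length(bed) == 1L) bed <- read_bed6(bed)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    gss <- Biostrings::readBStringSet(genome)
    names(gss) <- sub("\\s.*$", "", names(gss))
    genome <- stats::setNames(as.character(gss), names(gss))
  }
  stopifnot(is.character(genome), !is.null(names(genome)))
  widths <- bed$end - bed$start
  if (length(unique(widths)) > 1L) {
    stop_input("intervals have mixed widths; all must be equal")
  }
  strand <- ifelse(bed$strand == ".", "+", bed$strand)

  keep <- rep(TRUE, nrow(bed))
  missing_chrom <- !(bed$chrom %in% names(genome))
  if (any(missing_chrom)) {
    warn(paste0("dropping ", sum(missing_chrom),
                " record(s) on chromosomes absent from the genome"))
    keep[missing_chrom] <- FALSE
  }
  clen <- ifelse(keep, nchar(genome[bed$chrom]), NA_integer_)
  off_end <- keep & (bed$start < 0L | bed$end > clen)
  if (any(off_end)) {
    warn(paste0("dropping ", sum(off_end),
                " record(s) extending past chromosome ends"))
    keep[off_end] <- FALSE
  }
  if (!any(keep)) stop_input("all intervals were dropped")

  bed <- bed[keep, , drop = FALSE]
  strand <- strand[keep]
  seqs <- substr(genome[bed$chrom], bed$start + 1L, bed$end)
  minus <- strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])

  ids <- ifelse(is.na(bed$name) | bed$name %in% c("", "."),
                paste0(bed$chrom, ":", bed$start, "-", bed$end),
                bed$name)
  tibble(id = make.unique(ids), seq = unname(seqs), score = bed$score,
         chrom = bed$chrom, start = bed$start, end = bed$end,
         strand = strand)
}

#' Filter out degenerate, repeat-masked and overlapping sequences
#'
#' Removes sequences whose masked fraction -- `N` bases plus soft-masked
#' (lowercase) bases, divided by the sequence length -- exceeds
#' `max_masked_frac` (default 0.5, i.e. sequences containing more than 50%
#' repetitive or degenerate bases are dropped). Optionally deduplicates
#' overlapping genomic intervals by greedily keeping non-overlapping
#' records in descending `|score|` order (ties by chrom, then start).
#'
#' @param x Scored sequence tibble; interval columns `chrom`, `start`,
#'   `end` are required only when `dedupe = TRUE`.
#' @param max_masked_frac Maximum tolerated masked fraction in `[0, 1]`.
#' @param dedupe Drop overlapping intervals, keeping the strongest?
#' @return The filtered tibble (possibly empty, with a warning).
#' @export
filter_sequences <- function(x, max_masked_frac = 0.5, dedupe = FALSE) {
  validate_scored_seqs(x)
  stopifnot(max_masked_frac >= 0, max_masked_frac <= 1)
  if (nrow(x) == 0L) return(x)
  L <- nchar(x$seq[[1]])
  n_low <- nchar(gsub("[^a-z]", "", x$seq))
  n_N <- nchar(gsub("[^N]", "", x$seq))
  x <- x[(n_low + n_N) / L <= max_masked_frac, , drop = FALSE]

  if (dedupe && all(c("chrom", "start", "end") %in% names(x)) && nrow(x) > 0) {
    ord <- order(-abs(x$score), x$chrom, x$start)
    keep <- logical(nrow(x))
    kept_by_chrom <- list()
    for (i in ord) {
      ch <- x$chrom[i]
      iv <- kept_by_chrom[[ch]]
      overlaps <- !is.null(iv) &&
        any(x$start[i] < iv[, 2L] & iv[, 1L] < x$end[i])
      if (!overlaps) {
        keep[i] <- TRUE
        kept_by_chrom[[ch]] <- rbind(iv, c(x$start[i], x$end[i]))
      }
    }
    x <- x[keep, , drop = FALSE]
  }
  if (nrow(x) == 0L) warn("all sequences removed by filtering")
  x
}

#' Read motifs in JASPAR PFM format
#'
#' Accepts both the bracketed JASPAR dialect (`A [ 4 19 0 ]`) and plain
#' whitespace-separated count rows. Each record starts with a `>ID name`
#' header followed by four rows (A, C, G, T).
#'
#' @param path Path to a JASPAR-format motif file.
#' @return A named list of `motif_matrix` objects, each a list with
#'   elements `id`, `name` and `counts` (a 4 x k numeric matrix with rows
#'   A, C, G, T).
#' @export
read_jaspar <- function(path) {
  if (!file.exists(path)) stop_input(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- which(startsWith(lines, ">"))
  if (length(starts) == 0L) stop_input("no motif records found")
  ends <- c(starts[-1] - 1L, length(lines))
  motifs <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    toks <- strsplit(hdr, "\\s+")[[1]]
    id <- toks[1]
    name <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else id
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) < 4L) {
      stop_input(paste0("motif ", id, ": expected 4 count rows"))
    }
    rows <- parse_jaspar_rows(body[1:4], id)
    motifs[[i]] <- new_motif_matrix(id, name, rows)
  }
  stats::setNames(motifs, vapply(motifs, `[[`, character(1), "id"))
}

parse_jaspar_rows <- function(body, id) {
  bases <- c("A", "C", "G", "T")
  rows <- vector("list", 4L)
  labelled <- grepl("^[ACGTacgt]\\b|^[ACGTacgt]\\s*\\[", body)
  for (r in 1:4) {
    line <- body[r]
    base <- if (labelled[r]) toupper(substr(line, 1, 1)) else bases[r]
    nums <- regmatches(line, gregexpr(
      "[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?", line))[[1]]
    vals <- as.numeric(nums)
    idx <- match(base, bases)
    if (is.na(idx)) stop_input(paste0("motif ", id, ": unknown row label"))
    rows[[idx]] <- vals
  }
  if (any(vapply(rows, is.null, logical(1)))) {
    stop_input(paste0("motif ", id, ": missing a base row"))
  }
  lens <- vapply(rows, length, integer(1))
  if (length(unique(lens)) != 1L || lens[1] < 1L) {
    stop_input(paste0("motif ", id, ": count rows differ in length (",
                      paste(lens, collapse = ", "), ")"))
  }
  do.call(rbind, rows)
}

#' Construct a motif count matrix object
#'
#' @param id Motif identifier.
#' @param name Human-readable motif name.
#' @param counts 4 x k non-negative matrix of base counts (rows A, C, G, T).
#' @return A `motif_matrix` object.
#' @export
new_motif_matrix <- function(id, name, counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4L, ncol(counts) >= 1L, all(counts >= 0))
  if (any(colSums(counts) <= 0)) {
    stop_input(paste0("motif ", id, ": every column needs a positive entry"))
  }
  dimnames(counts) <- list(c("A", "C", "G", "T"), NULL)
  structure(list(id = id, name = name, counts = counts),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat("<motif_matrix> ", x$id, " (", x$name, "), width ",
      ncol(x$counts), "\n", sep = "")
  print(round(x$counts, 2))
  invisible(x)
}

#' Consensus sequence of a motif count matrix
#'
#' @param motif A `motif_matrix`.
#' @return A character scalar; ties go to the earlier base in A, C, G, T.
#' @export
motif_consensus <- function(motif) {
  paste(rownames(motif$counts)[apply(motif$counts, 2, which.max)],
        collapse = "")
}

#' Write motifs in JASPAR PFM format
#'
#' @param motifs List of `motif_matrix` objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_jaspar <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(paste0(">", m$id, " ", m$name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(paste0(b, " [ ",
                        paste(sprintf("%g", m$counts[b, ]), collapse = " "),
                        " ]"), con)
    }
  }
  invisible(path)
}
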