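# Rendering: per-motif multi-panel figures, the sortable HTML results
# table with sparklines, the HTML clustermap, TSV exports and the run
# manifest.

#' Max-pool downsampling of a heatmap for display
#'
#' Reduces an `n x L` matrix to `R x C` by max-pooling over contiguous
#' blocks (boundaries from an even integer partition). Maximum pooling
#' keeps sparse single motif hits visible after reduction: the global
#' maximum is never lost.
#'
#' @param mat Numeric matrix.
#' @param target_rows,target_cols Output dimensions (each at most the
#'   corresponding input dimension).
#' @return A `target_rows` x `target_cols` matrix.
#' @export
downsample_heatmap <- function(mat, target_rows, target_cols) {
  n <- nrow(mat); L <- ncol(mat)
  stopifnot(target_rows >= 1, target_cols >= 1,
            target_rows <= n, target_cols <= L)
  rb <- floor(seq(0, n, length.out = target_rows + 1))
  cb <- floor(seq(0, L, length.out = target_cols + 1))
  rows <- matrix(0, target_rows, L)
  for (i in seq_len(target_rows)) {
    block <- mat[(rb[i] + 1):rb[i + 1], , drop = FALSE]
    rows[i, ] <- apply(block, 2, max)
  }
  out <- matrix(0, target_rows, target_cols)
  for (j in seq_len(target_cols)) {
    block <- rows[, (cb[j] + 1):cb[j + 1], drop = FALSE]
    out[, j] <- apply(block, 1, max)
  }
  out
}

#' Diverging profile colour scale
#'
#' Maps correlation values onto a blue-white-red diverging palette with
#' white exactly at zero and symmetric limits `c(-limit, limit)`.
#'
#' @param r Numeric vector of correlation values.
#' @param limit Positive symmetric limit (values are clamped).
#' @return Character vector of hex colours.
#' @export
profile_color <- function(r, limit = 1) {
  stopifnot(limit > 0)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#FFFFFF", "#B2182B"))(511)
  idx <- round((pmin(pmax(r / limit, -1), 1) + 1) / 2 * 510) + 1
  pal[idx]
}

# information-content letter heights per column (2 - entropy, split by
# base probability); small pseudocount keeps empty columns finite
logo_heights <- function(motif, pseudo = 1e-6) {
  counts <- motif$counts + pseudo
  p <- sweep(counts, 2, colSums(counts), "/")
  ic <- 2 + colSums(p * log2(p))
  sweep(p, 2, ic, "*")
}

.logo_colors <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")

#' Motif logo plot (information-content scaled)
#'
#' @param motif A `motif_matrix`.
#' @return A ggplot object.
#' @export
plot_motif_logo <- function(motif) {
  H <- logo_heights(motif)
  k <- ncol(H)
  df <- purrr::map_dfr(seq_len(k), function(c) {
    h <- sort(H[, c])
    tibble(col = c, base = names(h), h = as.numeric(h),
           y0 = cumsum(c(0, as.numeric(h)))[seq_len(4)])
  })
  df <- df[df$h > 0.01, , drop = FALSE]
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$col - 0.45, xmax = .data$col + 0.45,
      ymin = .data$y0, ymax = .data$y0 + .data$h, fill = .data$base),
      alpha = 0.25) +
    ggplot2::geom_text(ggplot2::aes(
      x = .data$col, y = .data$y0 + .data$h / 2, label = .data$base,
      colour = .data$base, size = .data$h), fontface = "bold") +
    ggplot2::scale_size(range = c(1, 8), limits = c(0, 2), guide = "none") +
    ggplot2::scale_fill_manual(values = .logo_colors, guide = "none") +
    ggplot2::scale_colour_manual(values = .logo_colors, guide = "none") +
    ggplot2::scale_y_continuous(limits = c(0, 2), expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = "bits", title = motif$id) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot a positional profile with its confidence band
#'
#' @param object A `positional_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot positional_profile
#' @export
autoplot.positional_profile <- function(object, ...) {
  tb <- object$tbl
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$offset)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "grey80") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3,
                        colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$r), colour = "#B2182B") +
    ggplot2::labs(x = "offset from sequence center (bp)",
                  y = "partial correlation",
                  title = object$motif_id) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot a motif heatmap (downsampled, rows in descending score order)
#'
#' @param object A `motif_heatmap`.
#' @param max_rows,max_cols Display grid limits.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot motif_heatmap
#' @export
autoplot.motif_heatmap <- function(object, max_rows = 400,
                                   max_cols = 400, ...) {
  M <- object$smoothed
  R <- min(nrow(M), max_rows)
  C <- min(ncol(M), max_cols)
  D <- downsample_heatmap(M, R, C)
  cb <- floor(seq(0, ncol(M), length.out = C + 1))
  off_mid <- object$offsets[pmax(1, ceiling((cb[-1] + cb[-(C + 1)]) / 2))]
  df <- tidyr::expand_grid(row = seq_len(R), col = seq_len(C))
  df$offset <- off_mid[df$col]
  df$value <- as.vector(t(D))[(df$row - 1) * C + df$col]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 guide = "none") +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = "motif offset (bp)", y = "score rank") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Render the multi-panel figure for one motif
#'
#' Assembles, with aligned position and rank axes: the motif logo, the
#' smoothed motif-count track, the score-vs-rank line, the central
#' downsampled heatmap, the per-sequence motif-density panel along the
#' rank axis, and the positional profile with its confidence band.
#'
#' @param hm A `motif_heatmap`.
#' @param profile The matching `positional_profile`.
#' @param motif The `motif_matrix` (for the logo).
#' @param path Output image path (`.png` or `.pdf`).
#' @param width,height Figure size in inches.
#' @return The path, invisibly.
#' @export
render_motif_figure <- function(hm, profile, motif, path,
                                width = 9, height = 7) {
  n <- nrow(hm$raw)
  tb <- profile$tbl

  p_logo <- plot_motif_logo(motif)
  p_counts <- ggplot2::ggplot(tb, ggplot2::aes(.data$offset,
                                               .data$count_smoothed)) +
    ggplot2::geom_line(colour = "#255C99") +
    ggplot2::labs(x = NULL, y = "motifs") +
    ggplot2::theme_minimal(base_size = 9)
  rank_df <- tibble(rank = seq_len(n), score = hm$scores)
  p_score <- ggplot2::ggplot(rank_df, ggplot2::aes(.data$score,
                                                   .data$rank)) +
    ggplot2::geom_path(colour = "grey30") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "score", y = "score rank") +
    ggplot2::theme_minimal(base_size = 9)
  p_hm <- autoplot.motif_heatmap(hm)
  dens_w <- max(1L, round(n / 20))
  dens_df <- tibble(
    rank = seq_len(n),
    density = rolling_mean(as.numeric(rowSums(hm$raw > 0) > 0), dens_w))
  p_dens <- ggplot2::ggplot(dens_df, ggplot2::aes(.data$density,
                                                  .data$rank)) +
    ggplot2::geom_path(colour = "#109648") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "motif density", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
  p_prof <- autoplot.positional_profile(profile) +
    ggplot2::labs(title = NULL)

  design <- "F#BB##\nCCAADD\nCCAADD\n##EE##"
  fig <- patchwork::wrap_plots(
    A = p_hm, B = p_counts, C = p_score, D = p_dens, E = p_prof,
    F = p_logo, design = design) +
    patchwork::plot_annotation(title = paste0(hm$motif_id, " (",
                                              motif$name, ")"))
  save_figure(fig, path, width, height)
  invisible(path)
}

save_figure <- function(fig, path, width, height) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png" && !capabilities("png")) {
    path <- sub("\\.png$", ".pdf", path)
    ext <- "pdf"
  }
  suppressWarnings(ggplot2::ggsave(path, fig, width = width,
                                   height = height, dpi = 100))
  path
}

# ---- inline SVG helpers for the HTML reports -------------------------------

svg_sparkline <- function(tb, width = 220, height = 40) {
  L <- nrow(tb)
  lim <- max(abs(c(tb$r, tb$ci_low, tb$ci_high)), 0.01)
  sx <- function(i) sprintf("%.1f", (i - 1) / (L - 1) * width)
  sy <- function(v) sprintf("%.1f", (1 - (v / lim + 1) / 2) * height)
  band <- paste0(
    paste(sx(seq_len(L)), sy(tb$ci_high), sep = ",", collapse = " "), " ",
    paste(sx(rev(seq_len(L))), sy(rev(tb$ci_low)), sep = ",",
          collapse = " "))
  line <- paste(sx(seq_len(L)), sy(tb$r), sep = ",", collapse = " ")
  zero <- sy(0)
  paste0(
    "<svg width='", width, "' height='", height, "' viewBox='0 0 ", width,
    " ", height, "'>",
    "<polygon points='", band, "' fill='#dddddd'/>",
    "<line x1='0' y1='", zero, "' x2='", width, "' y2='", zero,
    "' stroke='#999999' stroke-width='0.5'/>",
    "<polyline points='", line,
    "' fill='none' stroke='#B2182B' stroke-width='1'/>",
    "</svg>")
}

svg_logo <- function(motif, width = 120, height = 40) {
  H <- logo_heights(motif)
  k <- ncol(H)
  cw <- width / k
  cells <- character(0)
  for (c in seq_len(k)) {
    h <- sort(H[, c])
    y <- height
    for (b in names(h)) {
      hh <- h[[b]] / 2 * height
      if (hh < 0.5) next
      y <- y - hh
      cells <- c(cells, sprintf(
        paste0("<rect x='%.1f' y='%.1f' width='%.1f' height='%.1f' ",
               "fill='%s' opacity='0.8'/>"),
        (c - 1) * cw, y, cw * 0.9, hh, .logo_colors[[b]]))
      if (hh > 8) {
        cells <- c(cells, sprintf(
          paste0("<text x='%.1f' y='%.1f' font-size='%.1f' fill='white' ",
                 "text-anchor='middle' font-family='monospace'>%s</text>"),
          (c - 0.55) * cw, y + hh * 0.8, min(hh, cw), b))
      }
    }
  }
  paste0("<svg width='", width, "' height='", height, "' viewBox='0 0 ",
         width, " ", height, "'>", paste(cells, collapse = ""), "</svg>")
}

.sort_js <- "
function sortTable(tbl, col) {
  var t = document.getElementById(tbl);
  var rows = Array.prototype.slice.call(t.tBodies[0].rows);
  var dir = t.getAttribute('data-dir') === 'asc' ? -1 : 1;
  t.setAttribute('data-dir', dir === 1 ? 'asc' : 'desc');
  rows.sort(function(a, b) {
    var x = a.cells[col].getAttribute('data-v');
    var y = b.cells[col].getAttribute('data-v');
    var nx = parseFloat(x), ny = parseFloat(y);
    if (!isNaN(nx) && !isNaN(ny)) return dir * (nx - ny);
    return dir * x.localeCompare(y);
  });
  rows.forEach(function(r) { t.tBodies[0].appendChild(r); });
}
"

#' Render the sortable HTML results table
#'
#' One row per motif: ID (hyperlinked to its figure when available), logo
#' thumbnail, profile sparkline with confidence band, and the profile
#' extrema (max/min r, their offsets and raw/BY-adjusted p-values).
#' Numeric cells use the same formatting as the TSV export, and the file
#' is fully self-contained (inline SVG, inline sort script).
#'
#' @param extrema Tibble from [profile_extrema()] rows, one per motif.
#' @param profiles Named list of `positional_profile` objects (for the
#'   sparklines), in the same order as `extrema`.
#' @param motifs Named list of `motif_matrix` objects.
#' @param path Output HTML path.
#' @param figure_paths Optional named character vector of per-motif
#'   figure paths (relative to the HTML file) used as hyperlink targets.
#' @return The path, invisibly.
#' @export
render_results_table <- function(extrema, profiles, motifs, path,
                                 figure_paths = NULL) {
  cols <- c("motif", "logo", "profile", "max_r", "max_offset", "max_p",
            "max_p_adj", "min_r", "min_offset", "min_p", "min_p_adj")
  head_cells <- paste0(sprintf(
    "<th onclick=\"sortTable('results',%d)\">%s</th>",
    seq_along(cols) - 1, cols), collapse = "")
  rows <- vapply(seq_len(nrow(extrema)), function(i) {
    id <- extrema$motif_id[i]
    fig <- figure_paths[[id]] %||% NULL
    id_cell <- if (!is.null(fig)) {
      sprintf("<a href='%s'>%s</a>", fig, id)
    } else id
    num <- function(col) {
      v <- extrema[[col]][i]
      sprintf("<td data-v='%s'>%s</td>", fmt_num(v), fmt_num(v))
    }
    paste0(
      "<tr>",
      sprintf("<td data-v='%s'>%s</td>", id, id_cell),
      sprintf("<td data-v='%s'>%s</td>", id, svg_logo(motifs[[id]])),
      sprintf("<td data-v='%s'>%s</td>", fmt_num(extrema$max_r[i]),
              svg_sparkline(profiles[[id]]$tbl)),
      num("max_r"), num("max_offset"), num("max_p"), num("max_p_adj"),
      num("min_r"), num("min_offset"), num("min_p"), num("min_p_adj"),
      "</tr>")
  }, character(1))
  html <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>Positional motif enrichment results</title>",
    "<style>body{font-family:sans-serif}table{border-collapse:collapse}",
    "th,td{border:1px solid #ccc;padding:4px 8px;text-align:right}",
    "th{cursor:pointer;background:#f0f0f0}</style>",
    paste0("<script>", .sort_js, "</script>"),
    "</head><body>",
    "<h1>Positional motif enrichment results</h1>",
    "<table id='results' data-dir='desc'><thead><tr>",
    head_cells, "</tr></thead><tbody>",
    rows,
    "</tbody></table></body></html>")
  writeLines(html, path)
  invisible(path)
}

# dendrogram segment coordinates from an hclust fit (leaves at y = 1..n,
# x = merge height)
dendrogram_segments <- function(hc) {
  n <- length(hc$order)
  leaf_y <- integer(n)
  leaf_y[hc$order] <- seq_len(n)
  node_y <- numeric(nrow(hc$merge))
  segs <- NULL
  pos <- function(v) if (v < 0) c(leaf_y[-v], 0) else c(node_y[v], hc$height[v])
  for (s in seq_len(nrow(hc$merge))) {
    a <- pos(hc$merge[s, 1]); b <- pos(hc$merge[s, 2])
    h <- hc$height[s]
    node_y[s] <- (a[1] + b[1]) / 2
    segs <- rbind(segs,
                  c(a[2], a[1], h, a[1]),
                  c(b[2], b[1], h, b[1]),
                  c(h, a[1], h, b[1]))
  }
  colnames(segs) <- c("x0", "y0", "x1", "y1")
  as.data.frame(segs)
}

#' Render the profile clustermap as self-contained HTML
#'
#' Motifs on the vertical axis in dendrogram leaf order, each profile a
#' row of colour bars on a diverging blue-white-red scale (white at
#' r = 0, symmetric limits at the largest `|r|` across all profiles),
#' with the UPGMA dendrogram alongside. Each row hyperlinks to the
#' motif's figure when available.
#'
#' @param clustering A `profile_clustering`.
#' @param profiles Named list of `positional_profile` objects.
#' @param path Output HTML path.
#' @param figure_paths Optional named character vector of figure paths.
#' @return The path, invisibly.
#' @export
render_clustermap <- function(clustering, profiles, path,
                              figure_paths = NULL) {
  ids <- clustering$leaf_order
  L <- nrow(profiles[[1]]$tbl)
  lim <- max(vapply(profiles, function(p) max(abs(p$tbl$r)), numeric(1)),
             0.01)
  row_h <- 14; cell_w <- max(1, round(600 / L)); dend_w <- 120
  label_w <- 160
  width <- dend_w + L * cell_w + label_w
  height <- length(ids) * row_h + 20

  rows_svg <- character(0)
  for (i in seq_along(ids)) {
    id <- ids[i]
    r <- profiles[[id]]$tbl$r
    cols <- profile_color(r, lim)
    y <- (i - 1) * row_h
    rects <- sprintf("<rect x='%d' y='%d' width='%d' height='%d' fill='%s'/>",
                     dend_w + (seq_len(L) - 1L) * cell_w, y, cell_w,
                     row_h - 1, cols)
    label <- sprintf(paste0("<text x='%d' y='%d' font-size='10' ",
                            "font-family='sans-serif'>%s</text>"),
                     dend_w + L * cell_w + 5, y + row_h - 4, id)
    row <- paste0(paste(rects, collapse = ""), label)
    fig <- figure_paths[[id]] %||% NULL
    if (!is.null(fig)) row <- paste0("<a href='", fig, "'>", row, "</a>")
    rows_svg <- c(rows_svg, row)
  }

  dend_svg <- ""
  if (!is.null(clustering$hclust)) {
    segs <- dendrogram_segments(clustering$hclust)
    hmax <- max(segs$x1, 1e-9)
    px <- function(h) sprintf("%.1f", (1 - h / hmax) * (dend_w - 10))
    py <- function(y) sprintf("%.1f", (y - 0.5) * row_h)
    dend_svg <- paste(sprintf(
      paste0("<line x1='%s' y1='%s' x2='%s' y2='%s' stroke='#333' ",
             "stroke-width='1'/>"),
      px(segs$x0), py(segs$y0), px(segs$x1), py(segs$y1)),
      collapse = "")
  }

  html <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>Positional profile clustermap</title></head><body>",
    "<h1>Positional profile clustermap</h1>",
    sprintf("<p>Diverging scale: blue = negative, white = 0, red = positive; limits &plusmn;%s</p>",
            fmt_num(lim)),
    sprintf("<svg width='%d' height='%d'>", width, height),
    dend_svg,
    rows_svg,
    "</svg></body></html>")
  writeLines(html, path)
  invisible(path)
}

#' Write a per-motif profile table as TSV
#'
#' Columns: offset, r, ci_low, ci_high, p, p_adj, count.
#'
#' @param profile A `positional_profile`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  tb <- profile$tbl
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("offset\tr\tci_low\tci_high\tp\tp_adj\tcount", con)
  writeLines(paste(tb$offset, fmt_num(tb$r), fmt_num(tb$ci_low),
                   fmt_num(tb$ci_high), fmt_num(tb$p), fmt_num(tb$p_adj),
                   tb$count, sep = "\t"), con)
  invisible(path)
}

#' Write the extrema summary table as TSV
#'
#' @param extrema Tibble of [profile_extrema()] rows.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_extrema_tsv <- function(extrema, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(extrema), collapse = "\t"), con)
  fmt_col <- function(v) {
    if (is.character(v)) v
    else if (is.integer(v)) as.character(v)
    else fmt_num(v)
  }
  cells <- vapply(extrema, fmt_col, character(nrow(extrema)))
  cells <- matrix(cells, nrow = nrow(extrema))
  lines <- apply(cells, 1, paste, collapse = "\t")
  writeLines(lines, con)
  invisible(path)
}
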