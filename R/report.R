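# Static HTML report: one self-contained page plus a figures/ directory.
# The report is a view of the tables written to disk, never a recomputation,
# and contains no timestamps so re-rendering the same result is
# byte-identical.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, max_rows = 500L) {
  if (is.null(df) || nrow(df) == 0L) return("<p class='stub'>No rows.</p>")
  truncated <- nrow(df) > max_rows
  df <- utils::head(df, max_rows)
  fmt <- function(v) {
    if (is.numeric(v)) formatC(v, format = "g", digits = 5) else as.character(v)
  }
  cells <- vapply(df, function(col) html_escape(fmt(col)), character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                  collapse = ""), "</tr>")
  body <- apply(cells, 1L, function(r)
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>"))
  note <- if (truncated)
    sprintf("<p class='stub'>Showing first %d rows; full table on disk.</p>",
            max_rows) else ""
  paste0("<table>", header, paste(body, collapse = "\n"), "</table>", note)
}

save_figure <- function(plot, path, width = 7, height = 4.5) {
  ok <- tryCatch({
    ggplot2::ggsave(path, plot = plot, width = width, height = height,
                    dpi = 110)
    TRUE
  }, error = function(e) FALSE)
  ok
}

figure_or_stub <- function(plot, fig_dir, name, out_dir, width = 7, height = 4.5) {
  path <- file.path(fig_dir, name)
  if (save_figure(plot, path, width, height))
    sprintf("<img src='figures/%s' alt='%s'/>", name, name)
  else
    "<p class='stub'>Figure could not be rendered on this system.</p>"
}

plot_beta_curve <- function(curve) {
  pts <- curve$points
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$beta, y = .data$r2)) +
    ggplot2::geom_hline(yintercept = curve$tau, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::labs(x = expression(beta), y = expression(R^2),
                  title = "Scale-free topology fit vs soft-threshold") +
    ggplot2::theme_minimal()
  if (!is.na(curve$selected_beta))
    p <- p + ggplot2::geom_vline(xintercept = curve$selected_beta,
                                 color = "firebrick", linetype = "dotted")
  p
}

plot_module_profiles <- function(expr, assignment, annotation = NULL,
                                 max_lines = 200L) {
  mods <- module_labels(assignment)
  rows <- list()
  mean_rows <- list()
  samples <- colnames(expr)
  for (m in mods) {
    members <- sort(names(assignment)[assignment == m])
    shown <- utils::head(members, max_lines)   # deterministic subsample
    sub <- expr[shown, , drop = FALSE]
    rows[[m]] <- data.frame(
      module = m,
      gene = rep(shown, times = ncol(sub)),
      sample = rep(samples, each = nrow(sub)),
      value = as.vector(sub), stringsAsFactors = FALSE)
    # mean profile over ALL members, not just the shown subsample
    mean_rows[[m]] <- data.frame(
      module = m, sample = samples,
      value = colMeans(expr[members, , drop = FALSE]),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  mdf <- do.call(rbind, mean_rows)
  df$sample <- factor(df$sample, levels = samples)
  mdf$sample <- factor(mdf$sample, levels = samples)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$value,
                                        group = .data$gene)) +
    ggplot2::geom_line(alpha = 0.25, color = "grey60", linewidth = 0.3) +
    ggplot2::geom_line(data = mdf,
                       mapping = ggplot2::aes(x = .data$sample,
                                              y = .data$value, group = 1),
                       color = "black", linewidth = 0.8) +
    ggplot2::facet_wrap(~module, scales = "free_y") +
    ggplot2::labs(x = "sample", y = "expression",
                  title = "Module expression profiles (black: module mean)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (!is.null(annotation)) {
    ann <- annotation[match(samples, annotation$sample_id), ]
    tick <- data.frame(sample = factor(samples, levels = samples),
                       class = ann$class_label)
    tick <- tick[!is.na(tick$class), , drop = FALSE]
    p <- p + ggplot2::geom_rug(
      data = tick, sides = "b", inherit.aes = FALSE,
      mapping = ggplot2::aes(x = .data$sample, color = .data$class)) +
      ggplot2::labs(color = "class")
  }
  p
}

plot_ora_bars <- function(ora_rows, top_per_module = 10L) {
  keep <- do.call(rbind, lapply(split(ora_rows, ora_rows$module),
                                utils::head, top_per_module))
  keep$neglog <- -log10(pmax(keep$p_adjust, 1e-300))
  keep$gene_set <- factor(keep$gene_set,
                          levels = rev(unique(keep$gene_set)))
  ggplot2::ggplot(keep, ggplot2::aes(x = .data$neglog, y = .data$gene_set)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = -log10(0.01), linetype = "dashed",
                        color = "grey40") +
    ggplot2::facet_wrap(~module, scales = "free_y") +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted P"), y = NULL,
                  title = "Over-representation (dashed line: adjusted P = 0.01)") +
    ggplot2::theme_minimal()
}

plot_gsea_heatmap <- function(gsea_rows) {
  ggplot2::ggplot(gsea_rows,
                  ggplot2::aes(x = .data$class, y = .data$module,
                               fill = .data$nes)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$p_adjust < 0.01, "*", "")), size = 6) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(title = "Module activity by class (NES; * adj. P < 0.01)",
                  x = "class", y = "module", fill = "NES") +
    ggplot2::theme_minimal()
}

plot_module_network <- function(graph) {
  nodes <- graph$nodes; edges <- graph$edges
  if (nrow(nodes) == 0L) return(NULL)
  # deterministic circular layout: no randomness, re-renders identically
  nodes <- nodes[order(nodes$gene), ]
  theta <- 2 * pi * (seq_len(nrow(nodes)) - 1) / nrow(nodes)
  nodes$x <- cos(theta); nodes$y <- sin(theta)
  eidx_a <- match(edges$gene_a, nodes$gene)
  eidx_b <- match(edges$gene_b, nodes$gene)
  seg <- data.frame(x = nodes$x[eidx_a], y = nodes$y[eidx_a],
                    xend = nodes$x[eidx_b], yend = nodes$y[eidx_b])
  lab <- nodes[nodes$labeled, , drop = FALSE]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          color = "grey80", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$degree,
                                     color = .data$origin)) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(x = .data$x * 1.12, y = .data$y * 1.12,
                                    label = .data$gene), size = 2.6) +
    ggplot2::scale_color_manual(values = c(module = "steelblue",
                                           interaction_added = "firebrick")) +
    ggplot2::labs(title = paste0("Module interaction network: ",
                                 nodes$module[1L]),
                  color = "origin", size = "degree") +
    ggplot2::theme_void()
}

#' Render the static HTML report
#'
#' Writes `report.html` and a `figures/` directory into `out_dir`. Sections
#' whose inputs were not provided (annotation, gene sets, interactions) are
#' replaced by explanatory stubs rather than omitted silently. Every number
#' shown is taken from the already-computed result tables; the report never
#' recomputes anything, and contains no timestamps, so re-rendering the
#' same result yields byte-identical HTML.
#'
#' @param result A `coex_result` from [run_pipeline()].
#' @param out_dir Output directory.
#' @return Path to `report.html`, invisibly.
#' @export
render_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fig_dir <- file.path(out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  s <- result$summary
  sec <- character()
  add <- function(title, body)
    sec <<- c(sec, sprintf("<section><h2>%s</h2>\n%s\n</section>", title, body))

  flat <- Filter(function(x) !is.list(x) && !is.null(x), s)
  summary_df <- data.frame(
    parameter = names(flat),
    value = vapply(flat, function(x) paste(format(x), collapse = ", "),
                   character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  add("Run summary", html_table(summary_df, max_rows = 100L))

  add("Soft-threshold selection",
      paste0(figure_or_stub(plot_beta_curve(result$beta_curve), fig_dir,
                            "beta_curve.png", out_dir),
             html_table(result$beta_curve$points)))

  mods <- module_labels(result$assignment)
  if (length(mods) > 0L) {
    add("Module expression profiles",
        figure_or_stub(plot_module_profiles(result$expr_filtered,
                                            result$assignment,
                                            result$annotation),
                       fig_dir, "module_profiles.png", out_dir,
                       width = 9, height = 6))
    adf <- data.frame(gene = names(result$assignment),
                      module = unname(result$assignment))
    adf <- adf[order(adf$module, adf$gene), ]
    add("Module assignment", html_table(adf))
    if (!is.null(result$hubs))
      add("Intramodular hubs", html_table(result$hubs))
  } else {
    add("Modules", "<p class='stub'>No co-expression modules were found.</p>")
  }

  if (!is.null(result$ora)) {
    ces_line <- if (!is.null(result$ces))
      sprintf("<p>Combined enrichment score (geometric mean of per-module best adjusted P): <b>%.4g</b></p>",
              result$ces$ces) else ""
    add("Over-representation analysis",
        paste0(ces_line,
               figure_or_stub(plot_ora_bars(result$ora), fig_dir,
                              "ora_bars.png", out_dir, width = 9, height = 6),
               html_table(result$ora)))
  } else {
    add("Over-representation analysis",
        "<p class='stub'>No gene set collection was provided; ORA was skipped.</p>")
  }

  if (!is.null(result$gsea)) {
    add("Gene set enrichment across classes",
        paste0(figure_or_stub(plot_gsea_heatmap(result$gsea), fig_dir,
                              "gsea_heatmap.png", out_dir),
               html_table(result$gsea)))
  } else {
    add("Gene set enrichment across classes",
        "<p class='stub'>No sample annotation was provided; GSEA was skipped.</p>")
  }

  if (!is.null(result$module_graphs)) {
    bodies <- vapply(names(result$module_graphs), function(m) {
      g <- result$module_graphs[[m]]
      if (nrow(g$nodes) == 0L)
        return(sprintf("<p class='stub'>%s: no interactions touch this module.</p>", m))
      p <- plot_module_network(g)
      paste0(figure_or_stub(p, fig_dir,
                            paste0("network_", m, ".png"), out_dir,
                            width = 6, height = 6),
             html_table(g$nodes, max_rows = 100L))
    }, character(1))
    add("Module interaction networks", paste(bodies, collapse = "\n"))
  } else {
    add("Module interaction networks",
        "<p class='stub'>No interaction file was provided; networks were skipped.</p>")
  }

  css <- paste(
    "body{font-family:sans-serif;max-width:1100px;margin:2em auto;color:#222}",
    "table{border-collapse:collapse;font-size:13px;margin:0.7em 0}",
    "th,td{border:1px solid #ccc;padding:3px 8px}",
    "th{background:#f0f0f0}",
    "img{max-width:100%}",
    ".stub{color:#777;font-style:italic}",
    "section{margin-bottom:2.5em}", sep = "\n")
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset='utf-8'/>",
    "<title>Co-expression module report</title>",
    "<style>", css, "</style></head>\n<body>",
    "<h1>Co-expression module analysis report</h1>\n",
    paste(sec, collapse = "\n"),
    "\n</body></html>\n")
  path <- file.path(out_dir, "report.html")
  writeLines(html, path)
  invisible(path)
}
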