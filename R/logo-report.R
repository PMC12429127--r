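# Percent-difference sequence logos with significance masking, heatmap
# rendering, and the consolidated run report.

#' Percent-difference logo matrix
#'
#' For every residue r and subsite s, the difference in percentage points
#' between the observed subsite frequency and the reference composition,
#' `diff = 100 * (f_obs - q)`, together with a two-sided exact binomial
#' test of the observed count against q at the subsite's defined-
#' observation count. Cells with p >= alpha are masked (excluded from
#' rendering). No multiple-testing correction is applied. Because both the
#' observed frequencies and the reference sum to 1 over the alphabet, each
#' subsite's differences sum to 0.
#'
#' @param matrix A `specificity_matrix` with count and frequency layers.
#' @param reference A `background_composition` giving the reference
#'   residue frequencies.
#' @param alpha Significance level for masking (default 0.05); `alpha >= 1`
#'   disables masking entirely.
#' @return A `logo_matrix`: list with `diff`, `pvals`, `masked` (20 x
#'   subsites), `alpha` and `subsites`.
#' @export
percent_difference_logo <- function(matrix, reference, alpha = 0.05) {
  stopifnot(inherits(matrix, "specificity_matrix"),
            inherits(reference, "background_composition"),
            alpha > 0, alpha <= 1)
  q <- reference$residue_freq[rownames(matrix$frequency)]
  diff <- 100 * sweep(matrix$frequency, 1L, q, "-")
  n <- matrix$n_defined
  pvals <- matrix(NA_real_, nrow = nrow(diff), ncol = ncol(diff),
                  dimnames = dimnames(diff))
  for (s in seq_along(n)) {
    if (n[s] < 1) next
    for (r in seq_len(nrow(diff))) {
      pvals[r, s] <- stats::binom.test(round(matrix$counts[r, s]), round(n[s]),
                                       p = q[r])$p.value
    }
  }
  masked <- if (alpha >= 1) {
    matrix(FALSE, nrow(diff), ncol(diff), dimnames = dimnames(diff))
  } else {
    is.na(pvals) | pvals >= alpha
  }
  structure(list(diff = diff, pvals = pvals, masked = masked,
                 alpha = alpha, subsites = matrix$subsites),
            class = "logo_matrix")
}

heatmap_palette <- function(layer) {
  if (layer == "zscore") {
    grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  } else {
    grDevices::colorRampPalette(c("#FFF5F0", "#67000D"))(101)
  }
}

#' Render a specificity-matrix layer as a heatmap
#'
#' Residues on rows (alphabetical), subsites P6 to P5' on columns, no
#' clustering; a diverging palette centred at zero for the Z-score layer
#' and a sequential one otherwise. Writes `<prefix>.png` always and
#' `<prefix>.svg` when the graphics device supports cairo.
#'
#' @param matrix A `specificity_matrix`.
#' @param layer One of `"counts"`, `"frequency"`, `"ratio"`, `"zscore"`.
#' @param path_prefix Output path without extension.
#' @param width,height Device size in inches.
#' @return Invisibly, the paths written.
#' @export
render_heatmap <- function(matrix, layer, path_prefix,
                           width = 7, height = 7) {
  stopifnot(inherits(matrix, "specificity_matrix"))
  m <- matrix[[layer]]
  if (is.null(m)) stop("layer not present: ", layer)
  m[!is.finite(m)] <- NA
  breaks <- if (layer == "zscore") {
    lim <- max(abs(m), 1e-9, na.rm = TRUE)
    seq(-lim, lim, length.out = 102)
  } else {
    seq(min(m, 0, na.rm = TRUE), max(m, 1e-9, na.rm = TRUE),
        length.out = 102)
  }
  ph <- pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                           color = heatmap_palette(layer), breaks = breaks,
                           main = layer, silent = TRUE)
  paths <- character(0)
  draw_to <- function(open_device, path) {
    open_device()
    on.exit(grDevices::dev.off(), add = TRUE)
    grid::grid.newpage()
    grid::grid.draw(ph$gtable)
    path
  }
  png_path <- paste0(path_prefix, ".png")
  paths <- c(paths, draw_to(function() {
    grDevices::png(png_path, width = width, height = height,
                   units = "in", res = 150)
  }, png_path))
  if (isTRUE(capabilities("cairo"))) {
    svg_path <- paste0(path_prefix, ".svg")
    paths <- c(paths, draw_to(function() {
      grDevices::svg(svg_path, width = width, height = height)
    }, svg_path))
  }
  invisible(paths)
}

#' Render a percent-difference logo as a diverging bar chart
#'
#' One panel per subsite: unmasked residues drawn as stacked letter bars,
#' enriched residues (positive percentage-point difference) above the
#' axis and depleted ones below, letter height proportional to the
#' difference magnitude.
#'
#' @param logo A `logo_matrix` from [percent_difference_logo()].
#' @param path_prefix Output path without extension.
#' @param width,height Device size in inches.
#' @return Invisibly, the paths written.
#' @export
render_logo <- function(logo, path_prefix, width = 9, height = 5) {
  stopifnot(inherits(logo, "logo_matrix"))
  draw <- function() {
    d <- logo$diff
    d[logo$masked] <- 0
    ns <- ncol(d)
    ylim <- range(c(colSums(pmax(d, 0)), -colSums(pmax(-d, 0)), 0))
    graphics::plot(NA, xlim = c(0.5, ns + 0.5), ylim = ylim * 1.05,
                   xlab = "subsite", ylab = "frequency difference (pp)",
                   xaxt = "n", bty = "l")
    graphics::axis(1, at = seq_len(ns), labels = logo$subsites)
    graphics::abline(h = 0, col = "grey40")
    for (s in seq_len(ns)) {
      for (sgn in c(1, -1)) {
        vals <- d[, s] * sgn
        idx <- order(vals[vals > 0], decreasing = TRUE)
        res <- names(vals[vals > 0])[idx]
        h <- vals[vals > 0][idx]
        base <- 0
        for (k in seq_along(res)) {
          mid <- sgn * (base + h[k] / 2)
          graphics::text(s, mid, res[k],
                         cex = max(0.4, min(2.5, h[k] / 3)),
                         col = if (sgn > 0) "#B2182B" else "#2166AC",
                         font = 2)
          base <- base + h[k]
        }
      }
    }
  }
  paths <- character(0)
  png_path <- paste0(path_prefix, ".png")
  grDevices::png(png_path, width = width, height = height,
                 units = "in", res = 150)
  draw()
  grDevices::dev.off()
  paths <- c(paths, png_path)
  if (isTRUE(capabilities("cairo"))) {
    svg_path <- paste0(path_prefix, ".svg")
    grDevices::svg(svg_path, width = width, height = height)
    draw()
    grDevices::dev.off()
    paths <- c(paths, svg_path)
  }
  invisible(paths)
}

#' Bundle run artifacts into a report directory
#'
#' Writes every supplied stage output to `out_dir` (TSV/JSON data
#' artifacts, heatmap and logo images), together with the effective
#' configuration, the package version and a machine-readable
#' `manifest.json` listing each written file with its MD5 checksum. Data
#' artifacts are deterministic, so re-running with the same inputs
#' reproduces identical checksums.
#'
#' @param out_dir Output directory (created if absent).
#' @param windows Optional window data frame.
#' @param matrix Optional `specificity_matrix` (all present layers are
#'   written; heatmaps rendered when `render = TRUE`).
#' @param background Optional `background_composition`.
#' @param pairs Optional `pair_matrix`.
#' @param lengths Optional `length_summary`.
#' @param missed Optional `missed_cleavage_report`.
#' @param logo Optional `logo_matrix`.
#' @param config Optional list of run parameters echoed into the manifest.
#' @param render Render images (default `TRUE`); data artifacts are
#'   written regardless.
#' @return Invisibly, the manifest as a list.
#' @export
run_report <- function(out_dir, windows = NULL, matrix = NULL,
                       background = NULL, pairs = NULL, lengths = NULL,
                       missed = NULL, logo = NULL, config = list(),
                       render = TRUE) {
  if (is.null(windows) && is.null(matrix) && is.null(background) &&
      is.null(pairs) && is.null(lengths) && is.null(missed) &&
      is.null(logo)) {
    stop("nothing to report: supply at least one stage output")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  add <- function(path) files <<- c(files, path)

  if (!is.null(windows)) {
    add(write_windows_tsv(windows, file.path(out_dir, "windows.tsv")))
  }
  if (!is.null(matrix)) {
    for (layer in intersect(c("counts", "frequency", "ratio", "zscore"),
                            names(matrix))) {
      p <- file.path(out_dir, paste0("matrix_", layer, ".tsv"))
      add(write_matrix_tsv(matrix, layer, p))
      if (isTRUE(render)) {
        add(render_heatmap(matrix, layer,
                           file.path(out_dir, paste0("heatmap_", layer))))
      }
    }
  }
  if (!is.null(background)) {
    add(write_background_tsv(background, file.path(out_dir, "background.tsv")))
  }
  if (!is.null(pairs)) {
    for (layer in intersect(c("counts", "zscore"), names(pairs))) {
      p <- file.path(out_dir, paste0("pairs_", layer, ".tsv"))
      m <- pairs[[layer]]
      utils::write.table(
        data.frame(p2 = rownames(m),
                   format(m, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE),
        p, sep = "\t", quote = FALSE, row.names = FALSE,
        fileEncoding = "UTF-8")
      add(p)
    }
  }
  if (!is.null(lengths)) {
    add(write_length_summary(lengths,
                             json_path = file.path(out_dir, "lengths.json"),
                             tsv_path = file.path(out_dir,
                                                  "length_histogram.tsv")))
  }
  if (!is.null(missed)) {
    p <- file.path(out_dir, "missed_cleavages.json")
    jsonlite::write_json(
      list(rule_residues = missed$rule_residues,
           n_peptides = missed$n_peptides,
           n_with_missed = missed$n_with_missed,
           fraction = missed$fraction),
      p, auto_unbox = TRUE, digits = NA)
    add(p)
  }
  if (!is.null(logo)) {
    p <- file.path(out_dir, "logo_diff.tsv")
    utils::write.table(
      data.frame(residue = rownames(logo$diff),
                 format(logo$diff, digits = 15, trim = TRUE,
                        scientific = FALSE),
                 check.names = FALSE),
      p, sep = "\t", quote = FALSE, row.names = FALSE,
      fileEncoding = "UTF-8")
    add(p)
    if (isTRUE(render)) {
      add(render_logo(logo, file.path(out_dir, "logo")))
    }
  }

  manifest <- list(
    package = "cleavemap",
    version = as.character(utils::packageVersion("cleavemap")),
    config = config,
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
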