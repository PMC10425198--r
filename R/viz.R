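#' Error-bar layer for significant features
#'
#' Computes the data layer of the per-feature error-bar figure: per-group
#' mean relative abundance (TSS scale) with its standard error, alongside the
#' DA effect (log2 fold change) and adjusted p-value, for features passing
#' the significance threshold. The layer is computed first and the figure is
#' drawn from it, so every plotted quantity is testable.
#'
#' @param abundance Abundance tibble.
#' @param metadata Metadata tibble.
#' @param results `da_results` for a single contrast on this table.
#' @param threshold Adjusted-p threshold (default 0.05).
#' @param order_by Feature ordering: `"p"` (ascending adjusted p), `"name"`,
#'   or `"group"` (sign of effect, then p); ties break by feature id.
#' @param select Optional feature subset to display.
#' @param max_features Hard cap on displayed features (default 30); more
#'   significant features than this is an error suggesting `select`.
#' @return A `pathway_errorbar` object: list with `layer` (tibble: feature,
#'   group, mean_rel_abundance, sem, effect, p_adjust, order) and the
#'   threshold; plot with [autoplot()][ggplot2::autoplot()] or [plot()].
#' @export
pathway_errorbar <- function(abundance, metadata, results, threshold = 0.05,
                             order_by = c("p", "name", "group"), select = NULL,
                             max_features = 30) {
  order_by <- match.arg(order_by)
  al <- align_samples(abundance, metadata)
  rel <- tss_normalize(al$abundance)
  res <- as_tibble(results)
  if (length(unique(paste(res$group1, res$group2))) > 1) {
    abort("results span several contrasts; filter to one before plotting")
  }
  missing_feats <- setdiff(res$feature, rel$feature)
  if (length(missing_feats) == nrow(res)) abort("results do not match the table's features")
  sig <- filter(res, .data$p_adjust < threshold)
  if (!is.null(select)) sig <- filter(sig, .data$feature %in% select)
  if (nrow(sig) == 0) abort("no feature passes the significance threshold")
  if (nrow(sig) > max_features) {
    abort(paste0(nrow(sig), " significant features exceed the display cap of ",
                 max_features, "; pass `select` to choose a subset"))
  }
  ord <- switch(order_by,
    p = order(sig$p_adjust, sig$feature),
    name = order(sig$feature),
    group = order(sign(sig$effect), sig$p_adjust, sig$feature))
  sig <- sig[ord, ]
  sig$order <- seq_len(nrow(sig))
  long <- rel |>
    filter(.data$feature %in% sig$feature) |>
    tidyr::pivot_longer(-"feature", names_to = "sample", values_to = "rel_abundance") |>
    left_join(select(al$metadata, "sample", "group"), by = "sample") |>
    group_by(.data$feature, .data$group) |>
    summarise(mean_rel_abundance = mean(.data$rel_abundance),
              sem = sd(.data$rel_abundance) / sqrt(n()), .groups = "drop")
  layer <- sig |>
    select("feature", "effect", "p_adjust", "order") |>
    left_join(long, by = "feature") |>
    arrange(.data$order, .data$group) |>
    select("feature", "group", "mean_rel_abundance", "sem", "effect",
           "p_adjust", "order")
  structure(list(layer = layer, threshold = threshold), class = "pathway_errorbar")
}

#' @method tidy pathway_errorbar
#' @export
tidy.pathway_errorbar <- function(x, ...) x$layer

#' @method autoplot pathway_errorbar
#' @export
autoplot.pathway_errorbar <- function(object, ...) {
  lay <- mutate(object$layer,
                feature = stats::reorder(.data$feature, -.data$order))
  ggplot2::ggplot(lay, ggplot2::aes(x = .data$mean_rel_abundance,
                                    y = .data$feature, fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$mean_rel_abundance - .data$sem,
                   xmax = .data$mean_rel_abundance + .data$sem),
      position = ggplot2::position_dodge(width = 0.8), height = 0.3) +
    ggplot2::labs(x = "relative abundance (mean ± SEM)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
plot.pathway_errorbar <- function(x, ...) print(autoplot(x, ...))

#' Principal-component layer of a feature table
#'
#' TSS-normalizes, centers each feature across samples, and takes the
#' singular value decomposition over samples. Variance fractions are the
#' normalized squared singular values. Features are not rescaled to unit
#' variance by default (relative abundances share a scale); set `scale` to
#' change that.
#'
#' @param abundance Abundance tibble.
#' @param metadata Metadata tibble.
#' @param k Number of components to keep (default 2); must not exceed the
#'   rank of the centered matrix.
#' @param scale Divide each centered feature by its standard deviation.
#' @return A `pathway_pca` object: list with `layer` (tibble: sample, group,
#'   PC1..PCk) and `variance_fraction` (full non-increasing spectrum).
#' @export
pathway_pca <- function(abundance, metadata, k = 2, scale = FALSE) {
  al <- align_samples(abundance, metadata)
  rel <- tss_normalize(al$abundance)
  m <- abd_matrix(rel)
  if (nrow(m) < 2 || ncol(m) < 2) abort("need at least 2 features and 2 samples")
  cm <- m - rowMeans(m)
  if (scale) {
    s <- apply(cm, 1, sd)
    cm[s > 0, ] <- cm[s > 0, , drop = FALSE] / s[s > 0]
  }
  sv <- svd(cm)
  lambda <- sv$d^2
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (k > rank) abort(paste0("k = ", k, " exceeds the rank (", rank, ") of the centered table"))
  varfrac <- lambda / sum(lambda)
  coords <- sv$v[, seq_len(k), drop = FALSE] * rep(sv$d[seq_len(k)], each = ncol(cm))
  colnames(coords) <- paste0("PC", seq_len(k))
  layer <- dplyr::bind_cols(
    tibble(sample = colnames(m)),
    as_tibble(coords)) |>
    left_join(select(al$metadata, "sample", "group"), by = "sample") |>
    dplyr::relocate("sample", "group")
  structure(list(layer = layer, variance_fraction = varfrac, k = k),
            class = "pathway_pca")
}

#' @method tidy pathway_pca
#' @export
tidy.pathway_pca <- function(x, ...) x$layer

#' @method glance pathway_pca
#' @export
glance.pathway_pca <- function(x, ...) {
  tibble(component = seq_along(x$variance_fraction),
         variance_fraction = x$variance_fraction)
}

#' @method autoplot pathway_pca
#' @export
autoplot.pathway_pca <- function(object, ...) {
  pct <- round(100 * object$variance_fraction[1:2], 1)
  p <- ggplot2::ggplot(object$layer,
                       ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$group))
  # normal-theory 95% ellipses need >= 3 samples per group
  if (min(table(object$layer$group)) >= 3) {
    p <- p + ggplot2::stat_ellipse(type = "norm", level = 0.95)
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = paste0("PC1 (", pct[1], "%)"),
                  y = paste0("PC2 (", pct[2], "%)")) +
    ggplot2::theme_minimal()
}

#' @export
plot.pathway_pca <- function(x, ...) print(autoplot(x, ...))

#' Row-standardized heatmap layer
#'
#' Z-scores every feature across samples (sample standard deviation);
#' constant rows become all-zero with a warning. Columns are ordered by group
#' and then by sample id — ordering is metadata-driven, never clustered.
#'
#' @param abundance Abundance tibble.
#' @param metadata Metadata tibble.
#' @param features Optional feature subset (error if empty or absent from
#'   the table).
#' @return A `pathway_heatmap` object: list with `layer` (tibble: feature,
#'   sample, group, z) and the column order.
#' @export
pathway_heatmap <- function(abundance, metadata, features = NULL) {
  al <- align_samples(abundance, metadata)
  m <- abd_matrix(al$abundance)
  if (!is.null(features)) {
    if (length(features) == 0) abort("empty feature selection")
    missing_feats <- setdiff(features, rownames(m))
    if (length(missing_feats)) {
      abort(paste0("feature(s) not in table: ", paste(missing_feats, collapse = ", ")))
    }
    m <- m[features, , drop = FALSE]
  }
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  if (any(s == 0)) {
    warn(paste0(sum(s == 0), " constant feature row(s) set to zero"))
  }
  z <- (m - mu) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  meta <- al$metadata
  col_order <- meta$sample[order(meta$group, meta$sample)]
  layer <- dplyr::bind_cols(tibble(feature = rownames(m)),
                            as_tibble(z, .name_repair = "minimal")) |>
    tidyr::pivot_longer(-"feature", names_to = "sample", values_to = "z") |>
    left_join(select(meta, "sample", "group"), by = "sample") |>
    mutate(sample = factor(.data$sample, levels = col_order)) |>
    arrange(.data$feature, .data$sample)
  structure(list(layer = layer, col_order = col_order), class = "pathway_heatmap")
}

#' @method tidy pathway_heatmap
#' @export
tidy.pathway_heatmap <- function(x, ...) x$layer

#' @method autoplot pathway_heatmap
#' @export
autoplot.pathway_heatmap <- function(object, ...) {
  ggplot2::ggplot(object$layer,
                  ggplot2::aes(x = .data$sample, y = .data$feature, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::facet_grid(~group, scales = "free_x", space = "free_x") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @export
plot.pathway_heatmap <- function(x, ...) print(autoplot(x, ...))

#' Write a figure to vector and raster files
#'
#' @param x A `pathway_errorbar`, `pathway_pca` or `pathway_heatmap` object.
#' @param path Output path without extension.
#' @param formats File formats to write (default `c("pdf", "png")`).
#' @param width,height,dpi Device settings.
#' @return Paths written, invisibly.
#' @export
write_figure <- function(x, path, formats = c("pdf", "png"), width = 7,
                         height = 5, dpi = 300) {
  p <- autoplot(x)
  paths <- vapply(formats, function(fmt) {
    f <- paste0(path, ".", fmt)
    suppressMessages(ggplot2::ggsave(f, p, width = width, height = height, dpi = dpi))
    f
  }, "")
  invisible(paths)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
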