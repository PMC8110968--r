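# ggplot2 views of the result objects.

#' @importFrom ggplot2 ggplot aes geom_tile geom_line geom_rug geom_hline
#'   scale_fill_gradient2 scale_fill_gradientn labs facet_wrap theme_minimal
#'   element_text theme
NULL

#' Heatmap of a sample correlation matrix
#'
#' @param object An `ecm_cor` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ecm_cor
#' @export
autoplot.ecm_cor <- function(object, ...) {
  df <- tidy(object)
  ord <- object$samples$sample_id
  df$sample_a <- factor(df$sample_a, levels = ord)
  df$sample_b <- factor(df$sample_b, levels = ord)
  ggplot(df, aes(x = .data$sample_a, y = .data$sample_b,
                 fill = .data$rho)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         midpoint = 0, limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "Spearman rho",
         title = paste0("Gene set: ", object$tag)) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5))
}

#' @rdname autoplot.ecm_cor
#' @method autoplot ecm_cor_panel
#' @export
autoplot.ecm_cor_panel <- function(object, ...) {
  df <- tidy(object)
  ord <- object[[1]]$samples$sample_id
  df$sample_a <- factor(df$sample_a, levels = ord)
  df$sample_b <- factor(df$sample_b, levels = ord)
  df$gene_set <- factor(df$gene_set, levels = names(object))
  ggplot(df, aes(x = .data$sample_a, y = .data$sample_b,
                 fill = .data$rho)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         midpoint = 0, limits = c(-1, 1)) +
    facet_wrap(~gene_set) +
    labs(x = NULL, y = NULL, fill = "Spearman rho") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, size = 5),
          axis.text.y = element_text(size = 5))
}

#' Region-mean heatmap of discovered epi-groups
#'
#' @param object An `ecm_epigroups` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ecm_epigroups
#' @export
autoplot.ecm_epigroups <- function(object, ...) {
  df <- object$regions
  df$population <- factor(df$population, levels = object$populations)
  ggplot(df, aes(x = .data$population, y = factor(.data$group),
                 fill = .data$mean_z)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         midpoint = 0) +
    labs(x = "epithelial population", y = "epi-group",
         fill = "mean z-score") +
    theme_minimal()
}

#' Running-sum enrichment plot
#'
#' @param object An `ecm_gsea` object.
#' @param set Name of the gene set to draw (default the first).
#' @param ... Unused.
#' @return A ggplot of the running enrichment score with hit positions.
#' @method autoplot ecm_gsea
#' @export
autoplot.ecm_gsea <- function(object, set = NULL, ...) {
  set <- set %||% object$table$set[1]
  prof <- gsea_es(object$ranked, object$gene_sets[[set]],
                  weight = object$weight)$running
  ggplot(prof, aes(x = .data$position, y = .data$running_sum)) +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_line(colour = "#2c7fb8") +
    geom_rug(data = prof[prof$hit, ], sides = "b") +
    labs(x = "rank in DP vs pan-DF list", y = "running enrichment score",
         title = set) +
    theme_minimal()
}

#' Deposition heatmap across the six BM zones
#'
#' @param deposition Tibble: `gene` plus one column per zone of relative
#'   values.
#' @return A ggplot tile map (genes x zones, 0-100 scale).
#' @export
plot_deposition_heatmap <- function(deposition) {
  df <- deposition |>
    tidyr::pivot_longer(-"gene", names_to = "zone", values_to = "relative")
  df$zone <- factor(df$zone, levels = zone_scheme())
  ggplot(df, aes(x = .data$zone, y = .data$gene, fill = .data$relative)) +
    geom_tile() +
    scale_fill_gradientn(colours = c("white", "#fee391", "#d95f0e"),
                         limits = c(0, 100)) +
    labs(x = "BM zone", y = NULL, fill = "relative\ndeposition") +
    theme_minimal() +
    theme(axis.text.y = element_text(size = 6))
}
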