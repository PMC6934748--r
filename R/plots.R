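# ggplot2 views of the main result types.

#' Plot melt curves
#'
#' Raw or normalized fluorescence against temperature, one line per
#' specimen.
#'
#' @param curves Long melt-curve tibble.
#' @param colour_by Optional tibble (`specimen_id`, `group`) used to
#'   colour lines (e.g. species calls).
#' @return A ggplot object.
#' @export
plot_melt_curves <- function(curves, colour_by = NULL) {
  if (!is.null(colour_by)) {
    curves <- left_join(curves, colour_by, by = "specimen_id")
    p <- ggplot(curves, aes(
      .data$temp_C, .data$fluorescence,
      group = .data$specimen_id, colour = .data$group
    ))
  } else {
    p <- ggplot(curves, aes(
      .data$temp_C, .data$fluorescence,
      group = .data$specimen_id
    ))
  }
  p + geom_line(alpha = 0.6) +
    labs(x = "Temperature (°C)", y = "Fluorescence") +
    theme_minimal()
}

#' Plot derivative melt curves (-dF/dT)
#'
#' The classic peak view: melting transitions appear as peaks, one trace
#' per specimen, with optional reference temperatures as dashed verticals.
#'
#' @param deriv Output of [melt_derivative()].
#' @param refs Optional named reference Tm vector to mark.
#' @inheritParams plot_melt_curves
#' @return A ggplot object.
#' @export
plot_derivative <- function(deriv, refs = NULL, colour_by = NULL) {
  if (!is.null(colour_by)) {
    deriv <- left_join(deriv, colour_by, by = "specimen_id")
    p <- ggplot(deriv, aes(
      .data$temp_C, .data$neg_dF_dT,
      group = .data$specimen_id, colour = .data$group
    ))
  } else {
    p <- ggplot(deriv, aes(
      .data$temp_C, .data$neg_dF_dT,
      group = .data$specimen_id
    ))
  }
  p <- p + geom_line(alpha = 0.6)
  if (!is.null(refs)) {
    p <- p + geom_vline(
      xintercept = unname(refs), linetype = "dashed", colour = "grey40"
    )
  }
  p + labs(x = "Temperature (°C)", y = "-dF/dT") + theme_minimal()
}

#' Tile view of polymorphic sites
#'
#' A compact alignment-figure style view: haplotypes as rows, polymorphic
#' columns as tiles coloured by base, faceted by species.
#'
#' @param haps Haplotype tibble from [collapse_haplotypes()].
#' @param sites Site classification from [classify_sites()]; only
#'   non-monomorphic columns are drawn.
#' @return A ggplot object.
#' @export
plot_sites <- function(haps, sites) {
  poly <- sites$position[sites$category != "monomorphic"]
  df <- purrr::list_rbind(purrr::map(seq_len(nrow(haps)), function(i) {
    tibble(
      haplotype_id = haps$haplotype_id[i],
      species = haps$species[i],
      position = poly,
      base = strsplit(haps$sequence[i], "", fixed = TRUE)[[1]][poly + 1]
    )
  }))
  ggplot(df, aes(factor(.data$position), .data$haplotype_id,
    fill = .data$base
  )) +
    geom_tile(colour = "white") +
    geom_text(aes(label = .data$base), size = 3) +
    facet_grid(rows = vars(.data$species), scales = "free_y", space = "free") +
    labs(x = "Alignment position (0-based)", y = NULL, fill = "Base") +
    theme_minimal()
}

#' @describeIn build_msn ggplot rendering of the network: nodes sized by
#'   haplotype count, coloured by melting temperature when annotated,
#'   tied alternative connections dashed. Uses an igraph layout when
#'   igraph is installed, otherwise a circular layout.
#' @param object A `haplotype_network`.
#' @param ... Unused.
#' @method autoplot haplotype_network
#' @export
autoplot.haplotype_network <- function(object, ...) {
  nodes <- object$nodes
  edges <- object$edges
  if (requireNamespace("igraph", quietly = TRUE) && nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(
      edges[c("from", "to", "weight")],
      directed = FALSE,
      vertices = nodes["haplotype_id"]
    )
    xy <- igraph::layout_with_fr(g, weights = edges$weight)
    nodes$x <- xy[, 1]
    nodes$y <- xy[, 2]
  } else {
    ang <- seq(0, 2 * pi, length.out = nrow(nodes) + 1)[seq_len(nrow(nodes))]
    nodes$x <- cos(ang)
    nodes$y <- sin(ang)
  }
  edges <- edges |>
    left_join(nodes[c("haplotype_id", "x", "y")],
      by = c(from = "haplotype_id")
    ) |>
    left_join(nodes[c("haplotype_id", "x", "y")],
      by = c(to = "haplotype_id"), suffix = c("", "_to")
    )
  p <- ggplot() +
    geom_segment(
      data = edges,
      aes(.data$x, .data$y,
        xend = .data$x_to, yend = .data$y_to,
        linetype = .data$alternative
      ),
      colour = "grey50"
    )
  if (all(is.na(nodes$tm_C))) {
    p <- p + geom_point(
      data = nodes,
      aes(.data$x, .data$y, size = .data$count, shape = .data$species)
    )
  } else {
    p <- p + geom_point(
      data = nodes,
      aes(.data$x, .data$y,
        size = .data$count, shape = .data$species,
        colour = .data$tm_C
      )
    ) +
      scale_colour_viridis_c(name = "Tm (°C)")
  }
  p +
    geom_text(
      data = nodes,
      aes(.data$x, .data$y, label = .data$haplotype_id),
      vjust = -1.2, size = 3
    ) +
    scale_size_area(max_size = 12) +
    scale_linetype_manual(
      values = c(`FALSE` = "solid", `TRUE` = "dashed"), guide = "none"
    ) +
    theme_void()
}

#' @describeIn score_and_rank Bar chart of each candidate's worst-case
#'   between-species melting separation.
#' @param object An `assay_ranking`.
#' @param ... Unused.
#' @method autoplot assay_ranking
#' @export
autoplot.assay_ranking <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(
    factor(.data$rank), .data$min_between_species_dtm_C,
    fill = factor(.data$amplicon_length)
  )) +
    geom_col() +
    labs(
      x = "Candidate rank", y = "Min between-species ΔTm (°C)",
      fill = "Amplicon (bp)"
    ) +
    theme_minimal()
}
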