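#' @importFrom ggplot2 autoplot ggplot aes
NULL

#' Plot a kinship distance-class profile
#'
#' Mean Loiselle kinship per distance class with the permutation envelope;
#' significant classes are marked.  Several profiles (e.g. ramet- and
#' genet-level) can be overlaid by row-binding them first.
#'
#' @param object An `sgs_profile` (or several row-bound profiles).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sgs_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot(df, aes(x = .data$d_mean, y = .data$fij, colour = .data$level)) +
    ggplot2::geom_ribbon(
      aes(ymin = .data$lower, ymax = .data$upper, fill = .data$level),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::geom_point(aes(shape = .data$significant), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 17, `FALSE` = 1)) +
    ggplot2::labs(x = "distance class mean (m)", y = expression(F[ij]),
                  colour = "level", fill = "level", shape = "significant") +
    ggplot2::theme_minimal()
}

#' Plot a genotype accumulation curve
#'
#' @param object A `genotype_accumulation` tibble.
#' @param ... Unused.
#' @return A ggplot (boxplots of genotype counts per locus-subset size).
#' @export
autoplot.genotype_accumulation <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot(df, aes(x = factor(.data$n_loci), y = .data$n_mlg)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "number of loci", y = "multilocus genotypes") +
    ggplot2::theme_minimal()
}

#' Map of genet footprints
#'
#' Footprint polygons (hulls and buffers) drawn in the internal metric
#' frame, in the field's conventional symbology: polygons for genets with
#' three or more ramets, distinct outlines for buffered singletons and
#' pairs.
#'
#' @param object A `genet_footprints` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.genet_footprints <- function(object, ...) {
  keep <- !vapply(object$polygon, is.null, logical(1))
  df <- purrr::map_dfr(which(keep), function(k) {
    poly <- object$polygon[[k]]
    tibble::tibble(
      mlg_id = object$mlg_id[k], method = object$method[k],
      x = poly[, 1L], y = poly[, 2L]
    )
  })
  ggplot(df, aes(x = .data$x, y = .data$y, group = .data$mlg_id,
                 colour = .data$method)) +
    ggplot2::geom_polygon(fill = NA) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "footprint") +
    ggplot2::theme_minimal()
}

#' Scatterplot of patch indices against patch area
#'
#' The three per-patch indices (richness, equitability, spatial mixing)
#' against patch area, with their fitted regression lines.
#'
#' @param object A `patch_stats` tibble (from [patch_stats()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_patch_regressions <- function(object, ...) {
  df <- object %>%
    dplyr::filter(!is.na(.data$a_p)) %>%
    tidyr::pivot_longer(c("r_p", "e_h", "s_mix"),
                        names_to = "index", values_to = "value")
  ggplot(df, aes(x = .data$a_p, y = .data$value,
                 colour = .data$index, shape = .data$index)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         aes(linetype = .data$index)) +
    ggplot2::labs(x = expression(A[P] ~ (m^2)), y = "index value") +
    ggplot2::theme_minimal()
}

#' Plot a genotypic richness surface
#'
#' @param object A `richness_surface`.
#' @param ... Unused.
#' @return A ggplot raster map; masked cells (areas without the species)
#'   are grey.
#' @export
autoplot.richness_surface <- function(object, ...) {
  ggplot(object$grid, aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(aes(fill = .data$value)) +
    ggplot2::scale_fill_distiller(palette = "RdYlGn", direction = -1,
                                  na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "local richness") +
    ggplot2::theme_minimal()
}

#' Histogram of pairwise allelic mismatches
#'
#' @param hist A tibble from [mismatch_histogram()].
#' @param ... Unused.
#' @return A ggplot bar chart over mismatch classes.
#' @export
plot_mismatch_histogram <- function(hist, ...) {
  ggplot(hist, aes(x = .data$mismatches, y = .data$n_pairs)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "allelic mismatches", y = "pairs") +
    ggplot2::theme_minimal()
}
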