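new_footprints <- function(df) {
  class(df) <- c("genet_footprints", class(df))
  df
}

joined_units <- function(data, partition) {
  dplyr::inner_join(
    data[c("sample_id", "x", "y", "patch_id")],
    as.data.frame(partition)[c("sample_id", "mlg_id", "n_g")],
    by = "sample_id"
  ) %>% dplyr::filter(!is.na(.data$mlg_id))
}

#' Convex hull footprints of multi-ramet genets
#'
#' Builds the convex hull polygon and area for every genet sampled at three
#' or more ramets.  A genet whose ramets are collinear has a zero-area hull
#' and is flagged with method `"collinear"` (no polygon); such genets are
#' rerouted to the two-ramet buffer rule by [genet_footprints()], using
#' their two most distant ramets.  Genets spanning several patches get a
#' single pooled hull.
#'
#' @param data A clone data tibble.
#' @param partition An `mlg_partition` from [assign_mlg()].
#' @return A `genet_footprints` tibble: `mlg_id, n_g, method, area,
#'   polygon` (list column of vertex matrices).
#' @export
genet_hulls <- function(data, partition) {
  units <- joined_units(data, partition) %>% dplyr::filter(.data$n_g >= 3L)
  if (nrow(units) == 0L) {
    return(new_footprints(tibble::tibble(
      mlg_id = character(), n_g = integer(), method = character(),
      area = numeric(), polygon = list()
    )))
  }
  res <- units %>%
    dplyr::group_by(.data$mlg_id, .data$n_g) %>%
    dplyr::group_map(function(d, key) {
      poly <- convex_hull_poly(d$x, d$y)
      tibble::tibble(
        mlg_id = key$mlg_id, n_g = key$n_g,
        method = if (is.null(poly)) "collinear" else "hull",
        area = if (is.null(poly)) 0 else polygon_area(poly),
        polygon = list(poly)
      )
    }) %>% dplyr::bind_rows() %>% dplyr::arrange(.data$mlg_id)
  if (any(res$method == "collinear")) {
    warning("collinear genet(s) with zero-area hull rerouted to buffer treatment: ",
            paste(res$mlg_id[res$method == "collinear"], collapse = ", "))
  }
  new_footprints(res)
}

#' Impute genet areas for under-sampled genets
#'
#' Convex hulls cannot be built for genets sampled at one or two ramets.
#' Their occupied area is imputed from the mean hull area of genets with
#' exactly three collected ramets (`A3`): singletons get `A3 / 3`, two-ramet
#' genets (and collinear multi-ramet genets) get `A3 / 1.5`.  Genets with a
#' proper hull keep their hull area unchanged.
#'
#' @param footprints Hull footprints from [genet_hulls()].
#' @param partition An `mlg_partition` from [assign_mlg()].
#' @param a3_override Mean three-ramet hull area to use when the data
#'   contain no three-ramet genet with positive hull area.
#' @return A tibble `mlg_id, n_g, method, area` covering every genet, with
#'   method `"hull"` or `"imputed_only"`; attribute `a3` records the mean
#'   used.
#' @export
impute_agen <- function(footprints, partition, a3_override = NULL) {
  three <- footprints %>%
    dplyr::filter(.data$n_g == 3L, .data$method == "hull", .data$area > 0)
  if (nrow(three) == 0L && is.null(a3_override)) {
    stop("no genet with exactly 3 ramets and positive hull area; ",
         "supply a3_override to impute areas")
  }
  a3 <- if (nrow(three) > 0L) mean(three$area) else a3_override
  sz <- clone_sizes(partition)
  hulled <- footprints %>% dplyr::filter(.data$method == "hull")
  out <- sz %>%
    dplyr::left_join(
      hulled[c("mlg_id", "area")] %>% dplyr::rename(hull_area = "area"),
      by = "mlg_id"
    ) %>%
    dplyr::mutate(
      method = dplyr::if_else(is.na(.data$hull_area), "imputed_only", "hull"),
      area = dplyr::case_when(
        !is.na(.data$hull_area) ~ .data$hull_area,
        .data$n_g == 1L ~ a3 / 3,
        TRUE ~ a3 / 1.5
      )
    ) %>%
    dplyr::select("mlg_id", "n_g", "method", "area")
  attr(out, "a3") <- a3
  out
}

#' Constant-area buffer footprints for one- and two-ramet genets
#'
#' Builds a polygon of prescribed area for each genet that lacks a convex
#' hull: a disc centred on the ramet for singletons, and a stadium (segment
#' buffer) around the two ramets for pairs, whose half-width `w` solves
#' `pi w^2 + 2 d w = target` for ramets a distance `d` apart.  Collinear
#' multi-ramet genets are buffered between their two most distant ramets.
#' Radii are solved against the discretized polygon area, so each polygon's
#' area matches its target to machine precision.
#'
#' @param data A clone data tibble.
#' @param partition An `mlg_partition` from [assign_mlg()].
#' @param target_area Named numeric vector of target areas (m^2) keyed by
#'   `mlg_id` (e.g. the `imputed_only` rows of [impute_agen()]), or a single
#'   number applied to all buffered genets.
#' @param n_segments Vertices used to discretize circular arcs.
#' @return A `genet_footprints` tibble with methods `"buffer_single"` /
#'   `"buffer_pair"`.
#' @export
buffer_polygons <- function(data, partition, target_area, n_segments = 64L) {
  if (any(target_area <= 0)) stop("target areas must be positive")
  units <- joined_units(data, partition)
  ids <- if (!is.null(names(target_area))) names(target_area) else {
    sz <- clone_sizes(partition)
    sz$mlg_id[sz$n_g <= 2L]
  }
  get_target <- function(id) {
    if (!is.null(names(target_area))) unname(target_area[[id]]) else target_area[1L]
  }
  res <- purrr::map_dfr(ids, function(id) {
    d <- units[units$mlg_id == id, ]
    if (nrow(d) == 0L) stop("unknown mlg_id in target_area: ", id)
    target <- get_target(id)
    if (nrow(d) == 1L) {
      poly <- disc_with_area(d$x, d$y, target, n_segments)
      method <- "buffer_single"
    } else {
      pts <- cbind(d$x, d$y)
      dm <- as.matrix(stats::dist(pts))
      far <- which(dm == max(dm), arr.ind = TRUE)[1L, ]
      p1 <- pts[far[1L], ]; p2 <- pts[far[2L], ]
      dd <- sqrt(sum((p2 - p1)^2))
      w <- stadium_halfwidth(dd, target, n_segments)
      poly <- stadium_poly(p1, p2, w, n_segments)
      method <- "buffer_pair"
    }
    tibble::tibble(
      mlg_id = id, n_g = d$n_g[1L], method = method,
      area = polygon_area(poly), polygon = list(poly)
    )
  })
  new_footprints(dplyr::arrange(res, .data$mlg_id))
}

#' Complete genet footprints
#'
#' Convenience assembly of the full footprint set: convex hulls for genets
#' with three or more non-collinear ramets, and constant-area buffer
#' polygons (disc or stadium) for the rest, with targets from the
#' three-ramet imputation rule of [impute_agen()].
#'
#' @inheritParams buffer_polygons
#' @param a3_override Passed to [impute_agen()].
#' @return A `genet_footprints` tibble covering every genet.
#' @export
genet_footprints <- function(data, partition, a3_override = NULL, n_segments = 64L) {
  hulls <- withCallingHandlers(
    genet_hulls(data, partition),
    warning = function(w) invokeRestart("muffleWarning")
  )
  agen <- impute_agen(hulls, partition, a3_override = a3_override)
  need_buffer <- agen$mlg_id[agen$method == "imputed_only"]
  proper <- hulls %>% dplyr::filter(.data$method == "hull")
  if (length(need_buffer) == 0L) return(new_footprints(proper))
  targets <- stats::setNames(
    agen$area[match(need_buffer, agen$mlg_id)], need_buffer
  )
  buf <- buffer_polygons(data, partition, targets, n_segments)
  out <- dplyr::bind_rows(proper, buf) %>% dplyr::arrange(.data$mlg_id)
  attr(out, "a3") <- attr(agen, "a3")
  new_footprints(out)
}

#' Inter-genet overlap report
#'
#' Exact polygon overlay of the (convex) genet footprints: pairwise
#' intersection areas, the union area, the percentage of the union covered
#' by two or more genets, and the maximum overlap multiplicity observed.
#'
#' @param footprints A `genet_footprints` tibble with polygons.
#' @param denominator `"union"` (default): percent overlap is relative to
#'   the union of all footprints; `"patches"`: relative to `patch_total`.
#' @param patch_total Total patch area (m^2) when `denominator = "patches"`.
#' @return An object of class `overlap_report`: list with `percent_overlap`,
#'   `union_area`, `area_ge2`, `max_multiplicity`, and `pairs` (tibble of
#'   positive pairwise overlaps).
#' @export
overlap_report <- function(footprints, denominator = c("union", "patches"),
                           patch_total = NULL) {
  denominator <- match.arg(denominator)
  keep <- !vapply(footprints$polygon, is.null, logical(1))
  if (any(!keep)) warning("degenerate footprint(s) skipped: ",
                          paste(footprints$mlg_id[!keep], collapse = ", "))
  fp <- footprints[keep, ]
  if (nrow(fp) < 2L) stop("overlap report needs at least 2 footprints")
  ov <- convex_overlay(fp$polygon)
  denom <- if (denominator == "union") ov$union_area else {
    if (is.null(patch_total)) stop("patch_total required for denominator = 'patches'")
    patch_total
  }
  pairs <- ov$pairs
  pairs$mlg_i <- fp$mlg_id[pairs$i]
  pairs$mlg_j <- fp$mlg_id[pairs$j]
  out <- list(
    percent_overlap = 100 * ov$area_ge2 / denom,
    union_area = ov$union_area,
    area_ge2 = ov$area_ge2,
    total_area = sum(fp$area),
    max_multiplicity = ov$max_multiplicity,
    denominator = denominator,
    pairs = pairs[c("mlg_i", "mlg_j", "area")]
  )
  class(out) <- "overlap_report"
  out
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Genet footprint overlap\n")
  cat(sprintf("  union area %.3f m^2; covered by >=2 genets: %.3f m^2 (%.2f%%)\n",
              x$union_area, x$area_ge2, x$percent_overlap))
  cat(sprintf("  max multiplicity %d; %d overlapping pair(s)\n",
              x$max_multiplicity, nrow(x$pairs)))
  invisible(x)
}

#' Patch areas from digitized outlines
#'
#' @param outlines A tibble of patch outline vertices with columns
#'   `patch_id, x, y` (vertices in drawing order per patch).
#' @return A tibble `patch_id, a_p` of planar polygon areas (m^2).
#' @export
patch_areas <- function(outlines) {
  stopifnot(all(c("patch_id", "x", "y") %in% names(outlines)))
  outlines %>%
    dplyr::group_by(.data$patch_id) %>%
    dplyr::group_map(function(d, key) {
      p <- cbind(d$x, d$y)
      if (nrow(p) < 3L) stop("outline of patch ", key$patch_id, " has fewer than 3 vertices")
      if (!is_simple_polygon(p)) {
        stop("self-intersecting outline for patch ", key$patch_id)
      }
      tibble::tibble(patch_id = key$patch_id, a_p = polygon_area(p))
    }) %>% dplyr::bind_rows()
}
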