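#' Genotypic spatial mixing index of a patch (S_mix)
#'
#' For each ramet in a patch, its nearest neighbour within the patch is
#' found (Euclidean distance, ties broken by smallest `sample_id`); `S_mix`
#' is the fraction of these directed nearest-neighbour relations that join
#' ramets of *different* genets: 0 when all ramets belong to one genet, 1
#' when every nearest neighbour is a different genet.  Its meaning is
#' inverse to the aggregation index: strong spatial mixing implies weak
#' clonemate aggregation.
#'
#' @param data A clone data tibble restricted to one patch (or with
#'   `patch` given).
#' @param partition An `mlg_partition` from [assign_mlg()].
#' @param patch Optional patch id to subset `data`.
#' @param mode `"directed"` (default; one relation per ramet, denominator
#'   `n`) or `"unordered"` (mutual nearest-neighbour pairs collapsed).
#' @return A single number in `[0, 1]`.
#' @export
smix <- function(data, partition, patch = NULL, mode = c("directed", "unordered")) {
  mode <- match.arg(mode)
  units <- joined_units(data, partition)
  if (!is.null(patch)) units <- units[units$patch_id == patch, ]
  if (nrow(units) < 2L) stop("S_mix needs at least 2 units in the patch")
  nn <- nearest_neighbours(units$x, units$y, units$sample_id)
  diff_genet <- units$mlg_id[nn] != units$mlg_id
  if (mode == "directed") return(mean(diff_genet))
  # unordered: collapse mutual pairs i <-> j into one
  a <- pmin(seq_along(nn), nn)
  b <- pmax(seq_along(nn), nn)
  key <- paste(a, b)
  keep <- !duplicated(key)
  mean(diff_genet[keep])
}

#' Per-patch genotypic indices
#'
#' For every patch with at least two admitted units: number of units and
#' genets, genotypic richness `R_p = (G_p - 1)/(n_p - 1)`, Shannon-Wiener
#' equitability of within-patch clone sizes, the spatial mixing index
#' `S_mix`, and (when outlines are supplied) patch area `A_P`.
#' Single-unit patches are excluded with a warning; patches without an
#' outline get `NA` area and are excluded from the area regressions.
#'
#' @param data A clone data tibble.
#' @param partition An `mlg_partition` from [assign_mlg()].
#' @param outlines Optional outline vertex tibble (see [patch_areas()]) or
#'   a precomputed tibble `patch_id, a_p`.
#' @return A tibble `patch_id, n, g, r_p, e_h, s_mix, a_p`.
#' @export
patch_stats <- function(data, partition, outlines = NULL) {
  units <- joined_units(data, partition)
  sizes <- units %>% dplyr::count(.data$patch_id, name = "n")
  small <- sizes$patch_id[sizes$n < 2L]
  if (length(small) > 0) {
    warning("patch(es) with a single admitted unit excluded: ",
            paste(small, collapse = ", "))
  }
  keep <- units %>% dplyr::filter(!.data$patch_id %in% small)
  res <- keep %>%
    dplyr::group_by(.data$patch_id) %>%
    dplyr::group_map(function(d, key) {
      ng <- as.integer(table(d$mlg_id))
      tibble::tibble(
        patch_id = key$patch_id,
        n = nrow(d),
        g = length(ng),
        r_p = genotypic_richness(nrow(d), length(ng)),
        e_h = equitability(ng),
        s_mix = {
          nn <- nearest_neighbours(d$x, d$y, d$sample_id)
          mean(d$mlg_id[nn] != d$mlg_id)
        }
      )
    }) %>% dplyr::bind_rows()
  if (!is.null(outlines)) {
    ap <- if (all(c("patch_id", "a_p") %in% names(outlines)) && !"x" %in% names(outlines)) {
      outlines
    } else {
      patch_areas(outlines)
    }
    res <- dplyr::left_join(res, ap, by = "patch_id")
    if (any(is.na(res$a_p))) {
      warning("patch(es) without outline get NA area: ",
              paste(res$patch_id[is.na(res$a_p)], collapse = ", "))
    }
  } else {
    res$a_p <- NA_real_
  }
  res
}

#' Univariate regressions of patch indices on patch area
#'
#' Ordinary least-squares fits of each genotypic index (`r_p`, `e_h`,
#' `s_mix`) on patch area `a_p`, with the Pearson correlation and its
#' two-sided p-value from the t distribution on `n - 2` degrees of
#' freedom.  Patches with missing area are dropped.
#'
#' @param stats A patch statistics tibble from [patch_stats()].
#' @return A tibble of class `patch_regressions`: `response, slope,
#'   intercept, r, p_value, n`.
#' @export
patch_regressions <- function(stats) {
  complete <- stats %>% dplyr::filter(!is.na(.data$a_p))
  if (nrow(complete) < 3L) stop("need at least 3 patches with area")
  if (stats::sd(complete$a_p) == 0) stop("patch areas have zero variance")
  out <- purrr::map_dfr(c("r_p", "e_h", "s_mix"), function(resp) {
    yv <- complete[[resp]]
    fit <- stats::lm(yv ~ a_p, data = complete)
    if (stats::sd(yv) == 0) {
      warning("response ", resp, " has zero variance; correlation undefined")
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(complete$a_p, yv)
      r <- unname(ct$estimate); p <- ct$p.value
    }
    tibble::tibble(
      response = resp,
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      r = r,
      p_value = p,
      n = nrow(complete)
    )
  })
  class(out) <- c("patch_regressions", class(out))
  out
}

#' @export
print.patch_regressions <- function(x, ...) {
  cat("Patch index regressions on patch area\n")
  for (k in seq_len(nrow(x))) {
    cat(sprintf("  %-5s r = %.3f; p = %s (n = %d)\n",
                x$response[k], x$r[k], format_pval(x$p_value[k]), x$n[k]))
  }
  invisible(x)
}

# p-values printed to 3 dp but never as exactly 0.
format_pval <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}

#' Local genotypic richness surface
#'
#' For every ramet, local genotypic richness is computed over the units
#' within `radius` metres (including itself): `(G_local - 1)/(N_local - 1)`,
#' defined as 0 for isolated units.  The values are interpolated onto a
#' regular grid by inverse-distance weighting; grid cells farther than
#' `mask_radius` from any unit are masked (areas without the species).  The
#' interpolant reproduces the input values at the data points.
#'
#' @param data A clone data tibble.
#' @param partition An `mlg_partition` from [assign_mlg()].
#' @param radius Neighbourhood radius in metres.
#' @param grid_resolution Grid cell size in metres.
#' @param mask_radius Masking distance (defaults to `radius`).
#' @param idw_power Inverse-distance weighting exponent.
#' @return An object of class `richness_surface`: list with `points`
#'   (per-ramet local richness) and `grid` (tibble `x, y, value, masked`).
#' @export
richness_surface <- function(data, partition, radius = 1, grid_resolution = 0.5,
                             mask_radius = NULL, idw_power = 2) {
  if (radius <= 0) stop("radius must be positive")
  if (is.null(mask_radius)) mask_radius <- radius
  units <- joined_units(data, partition)
  if (nrow(units) < 1L) stop("no admitted units")
  d <- as.matrix(stats::dist(cbind(units$x, units$y)))
  local <- vapply(seq_len(nrow(units)), function(i) {
    nb <- which(d[i, ] <= radius)
    n_local <- length(nb)
    if (n_local <= 1L) return(0)
    g_local <- dplyr::n_distinct(units$mlg_id[nb])
    (g_local - 1) / (n_local - 1)
  }, numeric(1))
  pts <- tibble::tibble(sample_id = units$sample_id, x = units$x,
                        y = units$y, richness = local)
  gx <- seq(min(units$x) - radius, max(units$x) + radius, by = grid_resolution)
  gy <- seq(min(units$y) - radius, max(units$y) + radius, by = grid_resolution)
  grid <- tidyr::expand_grid(x = gx, y = gy)
  val <- numeric(nrow(grid))
  masked <- logical(nrow(grid))
  px <- units$x; py <- units$y
  for (k in seq_len(nrow(grid))) {
    dx <- grid$x[k] - px; dy <- grid$y[k] - py
    dd <- sqrt(dx^2 + dy^2)
    if (min(dd) > mask_radius) {
      masked[k] <- TRUE
      val[k] <- NA_real_
    } else if (min(dd) < 1e-9) {
      val[k] <- local[which.min(dd)]
    } else {
      w <- 1 / dd^idw_power
      val[k] <- sum(w * local) / sum(w)
    }
  }
  grid$value <- val
  grid$masked <- masked
  out <- list(points = pts, grid = grid, radius = radius,
              grid_resolution = grid_resolution)
  class(out) <- "richness_surface"
  out
}

#' Evaluate a richness surface's interpolant at arbitrary points
#'
#' @param surface A `richness_surface`.
#' @param x,y Coordinates at which to evaluate.
#' @param idw_power Inverse-distance weighting exponent (matching the one
#'   used to build the surface).
#' @return Numeric vector of interpolated values.
#' @export
interpolate_richness <- function(surface, x, y, idw_power = 2) {
  px <- surface$points$x; py <- surface$points$y
  v <- surface$points$richness
  vapply(seq_along(x), function(k) {
    dd <- sqrt((x[k] - px)^2 + (y[k] - py)^2)
    if (min(dd) < 1e-9) return(v[which.min(dd)])
    w <- 1 / dd^idw_power
    sum(w * v) / sum(w)
  }, numeric(1))
}
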