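#' Configuration for the clonal population simulator
#'
#' Defaults emulate the studied sage population: 240 genets genotyped at 8
#' microsatellite loci with 8, 5, 4, 7, 16, 11, 14 and 8 alleles, clone
#' sizes following a truncated Pareto law (tail exponent 0.69, largest
#' clone capped at 55 ramets) dominated by small clones, and a phalanx
#' architecture (compact clones at constant within-clone density,
#' sigma = 0.25 m, with a 1.5 m exclusion distance between genet founding
#' points) in a 40 x 40 m arena, sized so the occupied area is a few
#' hundred square metres.  Guerrilla architecture uses a wide dispersal
#' scale and no exclusion, so genets intermingle.
#'
#' @param seed Integer seed; every draw of the simulator is reproducible
#'   under it.
#' @param arena Arena width and height in metres.
#' @param allele_counts Integer vector: number of alleles per locus (its
#'   length sets the number of loci).
#' @param n_genets Number of genets to found.
#' @param clone_sizes Optional explicit ramet counts per genet (overrides
#'   the Pareto law).
#' @param pareto_exponent Tail exponent of the clone-size law
#'   (`P(X >= x) ~ x^-beta`).
#' @param max_clone_size Truncation point of the clone-size law.
#' @param architecture `"phalanx"` or `"guerrilla"`.
#' @param sigma Dispersal scale of ramets around the genet seed point (m);
#'   defaults to 0.25 (phalanx) or 3 (guerrilla).
#' @param spread `"clone_size"` (default for phalanx): ramets are placed
#'   uniformly in a compact disc of radius `sigma * sqrt(n_g)` around the
#'   seed point, so a clone's occupied area grows in proportion to its
#'   ramet count at roughly constant within-clone density, as expected of
#'   phalanx growth; `"constant"` (default for guerrilla): isotropic
#'   Gaussian displacement with scale `sigma`, so genets intermingle.
#' @param exclusion Minimum distance between genet seed points (m);
#'   defaults to 1.5 (phalanx) or 0 (guerrilla).
#' @param mutation_rate Somatic mutation probability per allele copy per
#'   ramet (infinite-alleles: a mutation creates a new label).
#' @param selfing Probability that a founder's second allele copies the
#'   first (inbreeding in genotype generation; 0 = HWE).
#' @param dirichlet_alpha Concentration of the symmetric Dirichlet from
#'   which per-locus allele frequencies are drawn.
#' @return A `clone_sim_config` list.
#' @export
clone_sim_config <- function(seed = 1L,
                             arena = c(40, 40),
                             allele_counts = c(8L, 5L, 4L, 7L, 16L, 11L, 14L, 8L),
                             n_genets = 240L,
                             clone_sizes = NULL,
                             pareto_exponent = 0.69,
                             max_clone_size = 55L,
                             architecture = c("phalanx", "guerrilla"),
                             sigma = NULL,
                             spread = NULL,
                             exclusion = NULL,
                             mutation_rate = 0,
                             selfing = 0,
                             dirichlet_alpha = 1) {
  architecture <- match.arg(architecture)
  if (is.null(sigma)) sigma <- if (architecture == "phalanx") 0.25 else 3
  if (is.null(spread)) {
    spread <- if (architecture == "phalanx") "clone_size" else "constant"
  }
  spread <- match.arg(spread, c("clone_size", "constant"))
  if (is.null(exclusion)) exclusion <- if (architecture == "phalanx") 1.5 else 0
  stopifnot(sigma > 0, mutation_rate >= 0, mutation_rate <= 1,
            selfing >= 0, selfing <= 1, all(allele_counts >= 1))
  structure(list(
    seed = as.integer(seed), arena = arena, allele_counts = allele_counts,
    n_genets = as.integer(n_genets), clone_sizes = clone_sizes,
    pareto_exponent = pareto_exponent, max_clone_size = as.integer(max_clone_size),
    architecture = architecture, sigma = sigma, spread = spread,
    exclusion = exclusion,
    mutation_rate = mutation_rate, selfing = selfing,
    dirichlet_alpha = dirichlet_alpha
  ), class = "clone_sim_config")
}

rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

# Truncated discrete Pareto: P(X >= x) proportional to x^-beta on min..max.
sample_clone_sizes <- function(n, beta, max_size, min_size = 1L) {
  x <- seq.int(min_size, max_size)
  surv <- x^(-beta)
  pmf <- surv - c(surv[-1L], 0) # the truncation point absorbs the tail mass
  sample(x, n, replace = TRUE, prob = pmf / sum(pmf))
}

# Dart-throwing placement with a hard-core exclusion distance.
place_seeds <- function(n, arena, exclusion, max_tries = 200L) {
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      px <- stats::runif(1, 0, arena[1L]); py <- stats::runif(1, 0, arena[2L])
      if (i == 1L || exclusion <= 0 ||
          min((xs[seq_len(i - 1L)] - px)^2 + (ys[seq_len(i - 1L)] - py)^2) >= exclusion^2) {
        xs[i] <- px; ys[i] <- py; placed <- TRUE; break
      }
    }
    if (!placed) {
      stop("could not place ", n, " genet seeds with exclusion ", exclusion,
           " m; reduce n_genets or enlarge the arena")
    }
  }
  cbind(xs, ys)
}

#' Simulate a spatially explicit clonal population
#'
#' Draws per-locus allele frequencies from a symmetric Dirichlet, founds
#' genet genotypes from them (HWE, or partial selfing), places genet seed
#' points uniformly with the configured hard-core exclusion, draws ramet
#' counts from the clone-size law, scatters ramets isotropically around
#' their seed, and applies infinite-alleles somatic mutations per allele
#' copy.  Fully reproducible under the config seed.
#'
#' @param config A [clone_sim_config()].
#' @return An object of class `clonal_population`: list with `ramets`
#'   (tibble `ramet_id, x, y, genet_id` plus locus allele columns), `seeds`
#'   (genet founding points), `freqs` (generating allele frequencies in
#'   [allele_freqs()] shape) and `config`.
#' @export
simulate_clonal_population <- function(config) {
  stopifnot(inherits(config, "clone_sim_config"))
  set.seed(config$seed)
  L <- length(config$allele_counts)
  loci <- sprintf("loc%02d", seq_len(L))
  freqs <- purrr::map_dfr(seq_len(L), function(j) {
    k <- config$allele_counts[j]
    tibble::tibble(
      locus = loci[j], allele = seq_len(k),
      freq = if (k == 1L) 1 else rdirichlet1(k, config$dirichlet_alpha),
      n_obs = NA_integer_
    )
  })
  g <- config$n_genets
  sizes <- if (!is.null(config$clone_sizes)) {
    stopifnot(length(config$clone_sizes) == g)
    as.integer(config$clone_sizes)
  } else {
    sample_clone_sizes(g, config$pareto_exponent, config$max_clone_size)
  }
  # founder genotypes
  geno <- matrix(NA_integer_, g, 2L * L)
  for (j in seq_len(L)) {
    p <- freqs$freq[freqs$locus == loci[j]]
    a1 <- sample.int(length(p), g, replace = TRUE, prob = p)
    a2 <- sample.int(length(p), g, replace = TRUE, prob = p)
    if (config$selfing > 0) {
      copy <- stats::runif(g) < config$selfing
      a2[copy] <- a1[copy]
    }
    geno[, 2L * j - 1L] <- pmin(a1, a2)
    geno[, 2L * j] <- pmax(a1, a2)
  }
  seeds <- place_seeds(g, config$arena, config$exclusion)
  genet_of <- rep(seq_len(g), times = sizes)
  n <- length(genet_of)
  if (config$spread == "clone_size") {
    # compact clone: ramets uniform in a disc whose area grows with n_g,
    # i.e. roughly constant within-clone ramet density
    r_max <- config$sigma * sqrt(sizes)[genet_of]
    rr <- r_max * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    rx <- seeds[genet_of, 1L] + rr * cos(th)
    ry <- seeds[genet_of, 2L] + rr * sin(th)
  } else {
    rx <- seeds[genet_of, 1L] + stats::rnorm(n, 0, config$sigma)
    ry <- seeds[genet_of, 2L] + stats::rnorm(n, 0, config$sigma)
  }
  gm <- geno[genet_of, , drop = FALSE]
  if (config$mutation_rate > 0) {
    next_allele <- max(gm) # new labels above every founder label
    hits <- which(stats::runif(length(gm)) < config$mutation_rate)
    if (length(hits) > 0) {
      gm[hits] <- next_allele + seq_along(hits)
    }
  }
  ramets <- tibble::tibble(
    ramet_id = sprintf("R%05d", seq_len(n)),
    x = rx, y = ry,
    genet_id = sprintf("G%04d", genet_of)
  )
  colnames(gm) <- locus_cols(loci)
  ramets <- dplyr::bind_cols(ramets, tibble::as_tibble(gm))
  structure(list(ramets = ramets, seeds = seeds, freqs = freqs,
                 config = config),
            class = "clonal_population")
}

#' Use all simulated ramets as a clone data table
#'
#' Converts the full ramet set of a simulated population (a census rather
#' than a grid sample) into the clone data format, e.g. for studying an
#' analysis stage free of sampling effects.
#'
#' @param pop A `clonal_population`.
#' @return A clone data tibble; `patch_id` is `"all"` when patches have
#'   not been labelled.
#' @export
ramets_as_clone_data <- function(pop) {
  r <- pop$ramets
  out <- tibble::tibble(
    sample_id = r$ramet_id, x = r$x, y = r$y,
    patch_id = if ("patch_id" %in% names(r)) r$patch_id else "all"
  )
  dplyr::bind_cols(out, r[grep("^loc", names(r), value = TRUE)])
}

#' Label patches by spatial connectivity
#'
#' Groups ramets into patches as the single-linkage connected components
#' under a connectivity radius, and builds a (convex) outline per patch as
#' the hull of its ramets buffered outward by a margin.
#'
#' @param pop A `clonal_population`.
#' @param connectivity_radius Radius (m) under which two ramets are
#'   connected.
#' @param margin Outward buffer (m) applied to each patch hull.
#' @return The population with `ramets$patch_id` filled in and an
#'   `outlines` tibble (`patch_id, area, polygon` list column) attached.
#' @export
label_patches <- function(pop, connectivity_radius = 1, margin = 0.25) {
  stopifnot(connectivity_radius > 0)
  r <- pop$ramets
  n <- nrow(r)
  d <- as.matrix(stats::dist(cbind(r$x, r$y)))
  hit <- which(d <= connectivity_radius & upper.tri(d), arr.ind = TRUE)
  comp <- uf_components(n, hit)
  grp <- match(comp, comp[!duplicated(comp)])
  pid <- sprintf("P%03d", grp)
  pop$ramets$patch_id <- pid
  pop$outlines <- purrr::map_dfr(unique(pid), function(p) {
    sel <- pid == p
    pts <- do.call(rbind, lapply(which(sel), function(i) {
      disc_poly(r$x[i], r$y[i], margin, 24L)
    }))
    poly <- convex_hull_poly(pts[, 1L], pts[, 2L])
    tibble::tibble(patch_id = p, area = polygon_area(poly), polygon = list(poly))
  }) %>% dplyr::arrange(.data$patch_id)
  pop
}

#' Remove young singleton genets from large patches
#'
#' Emulates the aging of a phalanx population in which developed patches no
#' longer admit new seedlings: in every patch whose outline area exceeds
#' the given quantile of patch areas, all ramets belonging to single-ramet
#' genets are removed.
#'
#' @param pop A patch-labelled `clonal_population` (see [label_patches()]).
#' @param area_quantile Patches above this quantile of outline area are
#'   purged (ignored when `min_area` is given).
#' @param min_area Absolute outline area (m^2) above which a patch is
#'   purged.
#' @return The population with the purged ramets dropped (outlines are
#'   kept; patch membership is unchanged).
#' @export
purge_young_genets <- function(pop, area_quantile = 0.5, min_area = NULL) {
  stopifnot(!is.null(pop$ramets$patch_id), !is.null(pop$outlines))
  thr <- if (!is.null(min_area)) min_area else {
    stats::quantile(pop$outlines$area, area_quantile)
  }
  big <- pop$outlines$patch_id[pop$outlines$area > thr]
  sz <- table(pop$ramets$genet_id)
  singletons <- names(sz)[sz == 1L]
  drop <- pop$ramets$patch_id %in% big & pop$ramets$genet_id %in% singletons
  pop$ramets <- pop$ramets[!drop, ]
  pop
}

#' Simulate an aged phalanx population
#'
#' Composes the two cohorts that an old, partially clonal phalanx
#' population carries: a cohort of established genets with Pareto clone
#' sizes placed with hard-core exclusion, and a cohort of young
#' single-ramet genets recruited in the surrounding areas.  After patch
#' labelling, patches whose outline area exceeds the median are stripped of
#' their young singleton genets (developed patches no longer admit
#' seedlings), so genotypic richness, evenness and spatial mixing all
#' decline with patch area.
#'
#' @param seed Integer seed.
#' @param n_old,n_young Genets in the established and young cohorts.
#' @param arena Arena side lengths (m).
#' @param connectivity_radius Patch connectivity radius (m).
#' @param min_area Patches larger than this (m^2) are purged of young
#'   singletons (passed to [purge_young_genets()]).
#' @return A patch-labelled, purged `clonal_population` (outlines reflect
#'   the pre-purge patches, as a field drawing would).
#' @export
simulate_aged_population <- function(seed, n_old = 20L, n_young = 260L,
                                     arena = c(30, 30),
                                     connectivity_radius = 1,
                                     min_area = 3) {
  set.seed(seed + 2L)
  old_sizes <- sample_clone_sizes(n_old, beta = 0.69, max_size = 40L, min_size = 8L)
  old <- simulate_clonal_population(clone_sim_config(
    seed = seed, n_genets = n_old, arena = arena, exclusion = 5,
    clone_sizes = old_sizes
  ))
  young <- simulate_clonal_population(clone_sim_config(
    seed = seed + 1L, n_genets = n_young, arena = arena,
    architecture = "guerrilla", sigma = 0.2, exclusion = 0,
    clone_sizes = rep(1L, n_young)
  ))
  young$ramets$genet_id <- sub("^G", "Y", young$ramets$genet_id)
  young$ramets$ramet_id <- sub("^R", "Q", young$ramets$ramet_id)
  pop <- old
  pop$ramets <- dplyr::bind_rows(old$ramets, young$ramets)
  pop <- label_patches(pop, connectivity_radius = connectivity_radius)
  purge_young_genets(pop, min_area = min_area)
}

#' Sample a simulated population on a 1-m grid
#'
#' Applies the field sampling protocol on a rectangular grid: for each
#' grid quadrant intersected by a patch outline, (1) if the patch covers
#' more than half the quadrant and extends beyond it, two ramets are
#' sampled; (2) if it covers at most half and extends beyond, one ramet;
#' (3) a patch lying wholly inside the quadrant contributes two ramets
#' regardless of its size.  Sampled ramets are drawn uniformly at random
#' among the patch's ramets inside the quadrant, capped by availability;
#' quadrants whose patch intersection holds no ramet are skipped with a
#' warning.  Per-quadrant ramet counts are recorded.
#'
#' @param pop A patch-labelled `clonal_population`.
#' @param grid Grid resolution in metres.
#' @param seed Optional integer seed for the sampling draws.
#' @return A list of class `clone_sample`: `data` (clone data tibble),
#'   `truth` (tibble `sample_id, ramet_id, genet_id`), and `quadrats`
#'   (tibble `qx, qy, patch_id, n_ramets, n_sampled`).
#' @export
grid_sample <- function(pop, grid = 1, seed = NULL) {
  stopifnot(!is.null(pop$ramets$patch_id), !is.null(pop$outlines))
  if (!is.null(seed)) set.seed(seed)
  r <- pop$ramets
  cell_area <- grid^2
  picks <- list()
  quad <- list()
  skipped <- 0L
  for (k in seq_len(nrow(pop$outlines))) {
    p <- pop$outlines$patch_id[k]
    poly <- pop$outlines$polygon[[k]]
    b <- bbox(poly)
    poly_area <- polygon_area(poly)
    cx <- seq(floor(b[1L] / grid), ceiling(b[3L] / grid) - 1L)
    cy <- seq(floor(b[2L] / grid), ceiling(b[4L] / grid) - 1L)
    pr <- which(r$patch_id == p)
    for (ix in cx) for (iy in cy) {
      cell <- rbind(
        c(ix * grid, iy * grid), c((ix + 1) * grid, iy * grid),
        c((ix + 1) * grid, (iy + 1) * grid), c(ix * grid, (iy + 1) * grid)
      )
      inter <- convex_clip(poly, cell)
      if (is.null(inter)) next
      cov <- polygon_area(inter)
      inside_cell <- cov >= poly_area - 1e-9
      n_take <- if (inside_cell) 2L else if (cov / cell_area > 0.5) 2L else 1L
      in_cell <- pr[r$x[pr] >= ix * grid & r$x[pr] < (ix + 1) * grid &
                    r$y[pr] >= iy * grid & r$y[pr] < (iy + 1) * grid]
      if (length(in_cell) == 0L) {
        skipped <- skipped + 1L
        next
      }
      take <- if (length(in_cell) <= n_take) in_cell else {
        sample(in_cell, n_take)
      }
      picks[[length(picks) + 1L]] <- take
      quad[[length(quad) + 1L]] <- tibble::tibble(
        qx = ix, qy = iy, patch_id = p,
        n_ramets = length(in_cell), n_sampled = length(take)
      )
    }
  }
  if (skipped > 0L) {
    warning(skipped, " quadrant(s) intersecting a patch held no ramet and were skipped")
  }
  idx <- unlist(picks)
  sel <- r[idx, ]
  data <- tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(nrow(sel))),
    x = sel$x, y = sel$y, patch_id = sel$patch_id
  )
  loci_cols <- setdiff(names(sel), c("ramet_id", "x", "y", "genet_id", "patch_id"))
  data <- dplyr::bind_cols(data, sel[loci_cols])
  structure(list(
    data = data,
    truth = tibble::tibble(sample_id = data$sample_id,
                           ramet_id = sel$ramet_id, genet_id = sel$genet_id),
    quadrats = dplyr::bind_rows(quad)
  ), class = "clone_sample")
}
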