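# A partition with prescribed clone membership over given coordinates.
fixture_partitioned <- function(groups, x, y) {
  # groups: integer genet index per unit; genotypes made identical within
  # groups and unique between them using two loci
  geno <- cbind(2L * groups - 1L, 2L * groups, rep(1L, length(groups)),
                rep(2L, length(groups)))
  d <- make_clone_data(geno, x = x, y = y)
  list(data = d, partition = assign_mlg(d))
}

test_that("convex hull footprints have the right areas", {
  fx <- fixture_partitioned(rep(1L, 3), x = c(0, 1, 0), y = c(0, 0, 1))
  h <- genet_hulls(fx$data, fx$partition)
  expect_equal(h$area, 0.5)
  expect_equal(h$method, "hull")

  fx2 <- fixture_partitioned(rep(1L, 4), x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(genet_hulls(fx2$data, fx2$partition)$area, 1)

  # oracle equivalence on random point sets
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(4:9, 1)
    x <- runif(n); y <- runif(n)
    fxr <- fixture_partitioned(rep(1L, n), x, y)
    hr <- genet_hulls(fxr$data, fxr$partition)
    ch <- grDevices::chull(x, y)
    expect_equal(hr$area, oracle_shoelace(cbind(x[ch], y[ch])),
                 tolerance = 1e-12)
  }

  # collinear ramets are flagged
  fx3 <- fixture_partitioned(rep(1L, 3), x = c(0, 1, 2), y = c(0, 0, 0))
  expect_warning(h3 <- genet_hulls(fx3$data, fx3$partition), "collinear")
  expect_equal(h3$method, "collinear")
})

test_that("area imputation applies the 3 and 1.5 divisors", {
  groups <- c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 4L, 4L)
  x <- c(0, 1, 0, 10, 11, 10, 20, 30, 31)
  y <- c(0, 0, 1, 0, 0, 1.2, 0, 0, 0)
  fx <- fixture_partitioned(groups, x, y)
  h <- genet_hulls(fx$data, fx$partition)
  ag <- impute_agen(h, fx$partition)
  a3 <- mean(h$area) # both hulled genets have exactly 3 ramets
  expect_equal(attr(ag, "a3"), a3)
  expect_equal(ag$area[ag$n_g == 1L], a3 / 3)
  expect_equal(ag$area[ag$n_g == 2L], a3 / 1.5)
  # hull areas untouched
  expect_equal(sort(ag$area[ag$method == "hull"]), sort(h$area))

  # no three-ramet genet: error unless an override is supplied
  fx2 <- fixture_partitioned(c(1L, 2L), x = c(0, 5), y = c(0, 0))
  h2 <- genet_hulls(fx2$data, fx2$partition)
  expect_error(impute_agen(h2, fx2$partition), "a3_override")
  ag2 <- impute_agen(h2, fx2$partition, a3_override = 0.6)
  expect_equal(ag2$area, c(0.2, 0.2))
})

test_that("buffer polygons hit their target areas", {
  # singleton disc: target pi -> radius about 1
  fx <- fixture_partitioned(1L, x = 2, y = 3)
  b <- buffer_polygons(fx$data, fx$partition, c(MLG001 = pi))
  expect_equal(b$method, "buffer_single")
  expect_equal(b$area, pi, tolerance = 1e-9)

  # pair at distance 2 with target pi + 4: continuous half-width is 1
  fx2 <- fixture_partitioned(c(1L, 1L), x = c(0, 2), y = c(0, 0))
  b2 <- buffer_polygons(fx2$data, fx2$partition, c(MLG001 = pi + 4),
                        n_segments = 512)
  expect_equal(b2$method, "buffer_pair")
  expect_equal(b2$area, pi + 4, tolerance = 1e-9)
  w <- (-2 + sqrt(4 + pi * (pi + 4))) / pi
  poly_w <- max(b2$polygon[[1]][, 2]) # max |y| equals the half-width
  expect_equal(poly_w, w, tolerance = 1e-3)

  # rotation/translation equivariance of the stadium area
  fx3 <- fixture_partitioned(c(1L, 1L), x = c(10, 10 + sqrt(2)),
                             y = c(-5, -5 + sqrt(2)))
  b3 <- buffer_polygons(fx3$data, fx3$partition, c(MLG001 = pi + 4))
  expect_equal(b3$area, pi + 4, tolerance = 1e-9)

  expect_error(buffer_polygons(fx$data, fx$partition, c(MLG001 = -1)),
               "positive")
})

test_that("assembled footprints cover every genet with matching areas", {
  set.seed(12)
  groups <- rep(1:6, times = c(5, 4, 3, 3, 2, 1))
  x <- runif(length(groups), 0, 30) + groups * 40
  y <- runif(length(groups), 0, 30)
  fx <- fixture_partitioned(groups, x, y)
  fp <- genet_footprints(fx$data, fx$partition)
  expect_equal(nrow(fp), 6L)
  expect_setequal(fp$method[fp$n_g >= 3], "hull")
  expect_setequal(fp$method[fp$n_g == 2], "buffer_pair")
  expect_setequal(fp$method[fp$n_g == 1], "buffer_single")
  # polygon areas agree with the recorded areas
  for (k in seq_len(nrow(fp))) {
    expect_equal(polygon_area(fp$polygon[[k]]), fp$area[k], tolerance = 1e-9)
  }
})

test_that("overlap accounting is exact on hand geometries", {
  sq <- function(x0, y0, w) {
    cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + w, y0 + w))
  }
  fp <- tibble::tibble(
    mlg_id = c("A", "B"), n_g = c(3L, 3L), method = "hull",
    area = c(1, 1), polygon = list(sq(0, 0, 1), sq(0.5, 0, 1))
  )
  ov <- overlap_report(fp)
  expect_equal(ov$union_area, 1.5, tolerance = 1e-12)
  expect_equal(ov$area_ge2, 0.5, tolerance = 1e-12)
  expect_equal(ov$percent_overlap, 100 * 0.5 / 1.5, tolerance = 1e-9)
  expect_equal(ov$max_multiplicity, 2L)
  expect_equal(nrow(ov$pairs), 1L)

  # disjoint: zero percent
  fp2 <- tibble::tibble(
    mlg_id = c("A", "B"), n_g = 3L, method = "hull", area = 1,
    polygon = list(sq(0, 0, 1), sq(5, 5, 1))
  )
  expect_equal(overlap_report(fp2)$percent_overlap, 0)

  # triple overlap: multiplicity 3 and inclusion-exclusion consistency
  fp3 <- tibble::tibble(
    mlg_id = c("A", "B", "C"), n_g = 3L, method = "hull", area = 1,
    polygon = list(sq(0, 0, 1), sq(0.5, 0, 1), sq(0.25, 0.25, 1))
  )
  ov3 <- overlap_report(fp3)
  expect_equal(ov3$max_multiplicity, 3L)
  expect_gt(ov3$area_ge2, 0)
  expect_lte(ov3$area_ge2, ov3$union_area)
})

test_that("overlap percent matches a Monte Carlo estimate for random discs", {
  set.seed(23)
  centers <- cbind(runif(6, 0, 4), runif(6, 0, 4))
  radii <- runif(6, 0.5, 1.2)
  polys <- lapply(1:6, function(i) {
    clonescape:::disc_poly(centers[i, 1], centers[i, 2], radii[i], 96L)
  })
  fp <- tibble::tibble(
    mlg_id = sprintf("G%d", 1:6), n_g = 3L, method = "hull",
    area = vapply(polys, polygon_area, numeric(1)), polygon = polys
  )
  ov <- overlap_report(fp)
  # Monte Carlo on the discretized polygons' bounding box
  npt <- 1e5
  px <- runif(npt, -1.3, 5.3); py <- runif(npt, -1.3, 5.3)
  box_area <- (5.3 + 1.3)^2
  counts <- rowSums(vapply(1:6, function(i) {
    (px - centers[i, 1])^2 + (py - centers[i, 2])^2 <= radii[i]^2
  }, logical(npt)))
  p_union <- mean(counts >= 1); p_ge2 <- mean(counts >= 2)
  se_u <- sqrt(p_union * (1 - p_union) / npt) * box_area
  se_2 <- sqrt(p_ge2 * (1 - p_ge2) / npt) * box_area
  # allow for both MC error and the 96-segment discretization
  expect_lt(abs(ov$union_area - p_union * box_area), 3 * se_u + 0.05)
  expect_lt(abs(ov$area_ge2 - p_ge2 * box_area), 3 * se_2 + 0.05)
})

test_that("patch areas come from the shoelace formula and reject bad outlines", {
  sq_outline <- tibble::tibble(
    patch_id = "p1", x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)
  )
  expect_equal(patch_areas(sq_outline)$a_p, 1)
  tri <- tibble::tibble(patch_id = "t", x = c(0, 2, 0), y = c(0, 0, 2))
  expect_equal(patch_areas(tri)$a_p, 2)

  set.seed(5)
  for (rep in 1:3) {
    # star-shaped random simple polygon
    th <- sort(runif(8, 0, 2 * pi))
    r <- runif(8, 0.5, 2)
    pol <- tibble::tibble(patch_id = "r", x = r * cos(th), y = r * sin(th))
    expect_equal(patch_areas(pol)$a_p,
                 oracle_shoelace(cbind(pol$x, pol$y)), tolerance = 1e-12)
  }

  bowtie <- tibble::tibble(
    patch_id = "bad", x = c(0, 1, 0, 1), y = c(0, 1, 1, 0)
  )
  expect_error(patch_areas(bowtie), "self-intersecting.*bad")
})
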