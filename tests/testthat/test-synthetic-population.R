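test_that("simulation is reproducible and mutation-free clones are identical", {
  cfg <- clone_sim_config(seed = 5, n_genets = 25, arena = c(15, 15),
                          max_clone_size = 10)
  pop1 <- simulate_clonal_population(cfg)
  pop2 <- simulate_clonal_population(cfg)
  expect_identical(pop1$ramets, pop2$ramets)
  expect_identical(pop1$freqs, pop2$freqs)

  # mu = 0: every genet is internally genotype-identical
  loc_cols <- grep("^loc", names(pop1$ramets), value = TRUE)
  by_genet <- split(pop1$ramets[loc_cols], pop1$ramets$genet_id)
  expect_true(all(vapply(by_genet, function(g) nrow(unique(g)) == 1L,
                         logical(1))))

  # somatic mutations create new labels and near-identical genotypes
  cfg_mu <- clone_sim_config(seed = 5, n_genets = 25, arena = c(15, 15),
                             max_clone_size = 10, mutation_rate = 0.002)
  pop_mu <- simulate_clonal_population(cfg_mu)
  expect_gt(max(as.matrix(pop_mu$ramets[loc_cols])), max(pop_mu$freqs$allele))
})

test_that("all-singleton populations give richness 1 through the pipeline", {
  cfg <- clone_sim_config(seed = 9, n_genets = 40, arena = c(20, 20),
                          clone_sizes = rep(1L, 40))
  d <- ramets_as_clone_data(simulate_clonal_population(cfg))
  p <- assign_mlg(d)
  expect_equal(diversity_stats(d, p)$richness, 1)
})

test_that("patch labelling matches a reachability oracle", {
  # two clusters far apart
  cfg <- clone_sim_config(seed = 10, n_genets = 2, arena = c(4, 4),
                          clone_sizes = c(5L, 5L), exclusion = 0.1)
  pop <- simulate_clonal_population(cfg)
  pop$ramets$x <- pop$ramets$x + ifelse(pop$ramets$genet_id == "G0001", 0, 50)
  pop <- label_patches(pop, connectivity_radius = 2)
  expect_equal(length(unique(pop$ramets$patch_id)), 2L)

  # one isolated ramet forms its own patch
  cfg1 <- clone_sim_config(seed = 11, n_genets = 3, arena = c(2, 2),
                           clone_sizes = c(1L, 1L, 1L), exclusion = 0)
  pop1 <- simulate_clonal_population(cfg1)
  pop1$ramets$x <- c(0, 10, 20)
  pop1$ramets$y <- 0
  pop1 <- label_patches(pop1, connectivity_radius = 1)
  expect_equal(length(unique(pop1$ramets$patch_id)), 3L)

  # oracle: breadth-first reachability on a random configuration
  cfg2 <- clone_sim_config(seed = 12, n_genets = 30, arena = c(12, 12),
                           clone_sizes = rep(2L, 30), exclusion = 0)
  pop2 <- label_patches(simulate_clonal_population(cfg2),
                        connectivity_radius = 1)
  xy <- cbind(pop2$ramets$x, pop2$ramets$y)
  n <- nrow(xy)
  adj <- as.matrix(stats::dist(xy)) <= 1
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      frontier <- i
      while (length(frontier) > 0) {
        comp[frontier] <- cid
        frontier <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
      }
    }
  }
  expect_equal(
    as.integer(table(factor(comp))[order(-table(factor(comp)))]),
    as.integer(table(pop2$ramets$patch_id)[order(-table(pop2$ramets$patch_id))])
  )
  # membership agrees up to labels
  expect_equal(length(unique(paste(comp, pop2$ramets$patch_id))),
               length(unique(comp)))
})

test_that("grid sampling follows the field criteria", {
  loci <- c(1L, 2L)
  # a patch covering ~75% of one quadrant but extending into the next:
  # 2 samples from the covered quadrant
  pop <- list(
    ramets = tibble::tibble(
      ramet_id = sprintf("R%d", 1:6),
      x = c(0.2, 0.5, 0.8, 0.95, 1.1, 1.3),
      y = rep(0.5, 6),
      genet_id = "G1",
      loc01_1 = 1L, loc01_2 = 2L,
      patch_id = "P001"
    ),
    outlines = tibble::tibble(
      patch_id = "P001", area = NA_real_,
      polygon = list(cbind(c(0.1, 1.4, 1.4, 0.1), c(0.05, 0.05, 0.95, 0.95)))
    )
  )
  pop$outlines$area <- polygon_area(pop$outlines$polygon[[1]])
  s <- grid_sample(pop, seed = 1)
  q0 <- s$quadrats[s$quadrats$qx == 0, ]
  q1 <- s$quadrats[s$quadrats$qx == 1, ]
  expect_equal(q0$n_sampled, 2L) # coverage 0.75 of quadrant 0
  expect_equal(q1$n_sampled, 1L) # coverage 0.35 of quadrant 1

  # a patch wholly inside a quadrant with a single ramet: capped at 1
  tiny <- list(
    ramets = tibble::tibble(
      ramet_id = "R1", x = 0.5, y = 0.5, genet_id = "G1",
      loc01_1 = 1L, loc01_2 = 1L, patch_id = "P001"
    ),
    outlines = tibble::tibble(
      patch_id = "P001", area = 0.01,
      polygon = list(cbind(c(0.45, 0.55, 0.55, 0.45), c(0.45, 0.45, 0.55, 0.55)))
    )
  )
  s2 <- grid_sample(tiny, seed = 2)
  expect_equal(nrow(s2$data), 1L)
})

test_that("the analysis chain recovers simulator truth at mutation zero", {
  cfg <- clone_sim_config(seed = 21, n_genets = 45, arena = c(18, 18),
                          max_clone_size = 12)
  pop <- label_patches(simulate_clonal_population(cfg))
  s <- suppressWarnings(grid_sample(pop, seed = 22))
  p <- assign_mlg(s$data)
  sz <- clone_sizes(p)

  truth <- s$truth
  expect_equal(nrow(sz), dplyr::n_distinct(truth$genet_id))
  true_sizes <- table(truth$genet_id)
  expect_equal(max(sz$n_g), max(as.integer(true_sizes)))

  # clonal subrange equals the brute-force truth on the sampled subset
  joined <- dplyr::inner_join(s$data, truth, by = "sample_id")
  best <- 0
  for (g in unique(joined$genet_id)) {
    sub <- joined[joined$genet_id == g, ]
    if (nrow(sub) >= 2) best <- max(best, max(stats::dist(cbind(sub$x, sub$y))))
  }
  expect_equal(clonal_subrange(s$data, p), best)

  # the recovered partition refines to the same grouping as the truth
  m <- dplyr::inner_join(as.data.frame(p), truth, by = "sample_id")
  expect_equal(
    dplyr::n_distinct(paste(m$mlg_id, m$genet_id)),
    dplyr::n_distinct(m$genet_id)
  )
})

test_that("estimated allele frequencies converge to the generating law", {
  cfg <- clone_sim_config(seed = 31, n_genets = 2000,
                          arena = c(60, 60), architecture = "guerrilla",
                          clone_sizes = rep(1L, 2000),
                          allele_counts = c(4L, 8L))
  pop <- simulate_clonal_population(cfg)
  d <- ramets_as_clone_data(pop)
  est <- allele_freqs(d, weighting = "per_ramet")
  truth <- pop$freqs
  m <- dplyr::inner_join(est, truth, by = c("locus", "allele"),
                         suffix = c("_est", "_true"))
  se <- sqrt(m$freq_true * (1 - m$freq_true) / (2 * 2000))
  expect_true(all(abs(m$freq_est - m$freq_true) <= 3 * se + 1e-12))
})

test_that("same seed gives bit-identical grid samples", {
  cfg <- clone_sim_config(seed = 41, n_genets = 20, arena = c(12, 12))
  pop <- label_patches(simulate_clonal_population(cfg))
  s1 <- suppressWarnings(grid_sample(pop, seed = 42))
  s2 <- suppressWarnings(grid_sample(pop, seed = 42))
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth, s2$truth)
})
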