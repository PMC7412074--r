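test_that("mismatch counts equal multiset comparison per locus", {
  one <- function(g1, g2) {
    d <- make_clone_data(rbind(g1, g2))
    mismatch_matrix(d)[1, 2]
  }
  expect_equal(one(c(100L, 102L), c(100L, 102L)), 0L)
  expect_equal(one(c(100L, 100L), c(102L, 104L)), 2L)
  expect_equal(one(c(100L, 102L), c(100L, 104L)), 1L)
  expect_equal(one(c(100L, 100L), c(100L, 104L)), 1L)
  expect_equal(one(c(100L, 104L), c(100L, 100L)), 1L)

  # oracle equivalence on random 8-locus pairs
  set.seed(11)
  for (rep in 1:20) {
    g1 <- sample(1:4, 16, replace = TRUE)
    g2 <- sample(1:4, 16, replace = TRUE)
    expect_equal(one(g1, g2), oracle_mismatch(g1, g2))
  }

  # full matrix on a random dataset vs pairwise oracle
  d <- random_clone_data(12, L = 5, k = 3, seed = 2)
  m <- mismatch_matrix(d)
  g <- genotype_matrix(d)
  for (i in 1:11) for (j in (i + 1):12) {
    expect_equal(m[i, j], oracle_mismatch(g[i, ], g[j, ]))
  }
  expect_true(all(m == t(m)))
  expect_true(all(diag(m) == 0))
})

test_that("mismatch histogram tabulates pair counts", {
  d <- make_clone_data(rbind(c(1L, 1L), c(1L, 1L)))
  h <- mismatch_histogram(mismatch_matrix(d))
  expect_equal(h$n_pairs[h$mismatches == 0], 1L)
  expect_equal(sum(h$n_pairs), 1L)

  # distances {0,1,1} -> bins {0:1, 1:2}
  d3 <- make_clone_data(rbind(c(1L, 2L), c(1L, 2L), c(1L, 3L)))
  h3 <- mismatch_histogram(mismatch_matrix(d3))
  expect_equal(h3$n_pairs, c(1L, 2L))
})

test_that("single-linkage genotype assignment and threshold chaining", {
  # t = 0: 3 identical + 2 distinct
  d <- make_clone_data(rbind(
    c(1L, 2L), c(1L, 2L), c(1L, 2L), c(3L, 3L), c(4L, 5L)
  ), loci = "locA")
  p <- assign_mlg(d)
  sz <- clone_sizes(p)
  expect_equal(nrow(sz), 3L)
  expect_equal(sort(sz$n_g), c(1L, 1L, 3L))
  expect_equal(max(sz$n_g), 3L)

  # chaining at t = 1: A-B = 1, B-C = 1, A-C = 2 -> one lineage
  d2 <- make_clone_data(rbind(c(1L, 1L), c(1L, 2L), c(2L, 2L)), loci = "locA")
  expect_equal(nrow(clone_sizes(assign_mlg(d2, threshold = 1))), 1L)
  expect_equal(nrow(clone_sizes(assign_mlg(d2, threshold = 0))), 3L)

  # invariant to row order and to coordinates
  d3 <- random_clone_data(25, L = 4, k = 3, seed = 5)
  p3 <- assign_mlg(d3)
  shuffled <- d3[sample(nrow(d3)), ]
  shuffled$x <- rev(shuffled$x)
  p3b <- assign_mlg(shuffled)
  m <- dplyr::inner_join(as.data.frame(p3), as.data.frame(p3b),
                         by = "sample_id")
  expect_equal(m$mlg_id.x, m$mlg_id.y)

  # group count nonincreasing in t
  counts <- vapply(0:5, function(t) {
    nrow(clone_sizes(assign_mlg(d3, threshold = t)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("units with missing calls are excluded and flagged", {
  d <- make_clone_data(rbind(c(1L, 2L), c(1L, 2L), c(NA, NA)))
  expect_warning(p <- assign_mlg(d), "missing")
  expect_true(is.na(p$mlg_id[p$sample_id == "s003"]))
  expect_equal(sum(!is.na(p$mlg_id)), 2L)
})

test_that("pgen follows the single-locus genotype probabilities", {
  f1 <- tibble::tibble(locus = "loc01", allele = 1:2, freq = 0.5, n_obs = 4L)
  dAA <- make_clone_data(rbind(c(1L, 1L)))
  expect_equal(pgen(dAA, f1, fis = 0), 0.25)
  expect_equal(pgen(dAA, f1, fis = 1), 0.5) # p^2 + p(1-p)
  dAB <- make_clone_data(rbind(c(1L, 2L)))
  expect_equal(pgen(dAB, f1, fis = 0), 0.5)
  expect_equal(pgen(dAB, f1, fis = 1), 0)

  # two loci multiply
  f2 <- dplyr::bind_rows(
    f1, tibble::tibble(locus = "loc02", allele = 1:2, freq = 0.5, n_obs = 4L)
  )
  d2 <- make_clone_data(rbind(c(1L, 1L, 1L, 2L)))
  expect_equal(pgen(d2, f2, fis = 0), 0.25 * 0.5)

  # fis = 0 equals the parameterised form at 0, exactly
  dr <- random_clone_data(10, L = 3, k = 4, seed = 3)
  fr <- allele_freqs(dr)
  expect_identical(pgen(dr, fr), pgen(dr, fr, fis = 0))

  # unknown allele is an error naming the locus
  d_bad <- make_clone_data(rbind(c(9L, 9L)))
  expect_error(pgen(d_bad, f1), "loc01")
})

test_that("psex is the binomial tail and matches Monte Carlo", {
  expect_equal(psex(0.5, 2, 2), 0.25)
  expect_equal(psex(0, 10, 1), 0)
  expect_equal(psex(0.2, 10, 1), 1 - 0.8^10)

  # monotone in p_gen, antitone in n
  p_grid <- seq(0.01, 0.99, by = 0.07)
  expect_true(all(diff(psex(p_grid, 20, 3)) >= 0))
  expect_true(all(diff(psex(0.3, 20, 1:20)) <= 0))

  # Monte Carlo oracle
  set.seed(21)
  draws <- stats::rbinom(1e5, size = 30, prob = 0.1)
  mc <- mean(draws >= 4)
  se <- sqrt(mc * (1 - mc) / 1e5)
  expect_lt(abs(psex(0.1, 30, 4) - mc), 3 * se)

  expect_error(psex(0.5, 3, 4), "n_copies")
})

test_that("clone confidence covers repeated genotypes with tiny Psex", {
  d <- random_clone_data(15, L = 6, k = 8, seed = 13)
  d <- dplyr::bind_rows(
    d,
    dplyr::mutate(d[1:3, ], sample_id = paste0("dup", 1:3))
  )
  p <- assign_mlg(d)
  cc <- clone_confidence(d, p)
  expect_equal(nrow(cc), 3L)
  expect_true(all(cc$n_g == 2L))
  expect_true(all(cc$pgen >= 0 & cc$pgen <= 1))
  expect_true(all(cc$psex >= 0 & cc$psex <= 1))
  expect_true(all(cc$psex < 0.05)) # 6 polymorphic loci make repeats near-certain clones
})

test_that("genotype accumulation is exact at full locus count", {
  d <- random_clone_data(30, L = 5, k = 6, seed = 17)
  acc <- genotype_accumulation(d, n_permutations = 20, seed = 1)
  full <- acc$n_mlg[acc$n_loci == 5]
  truth <- nrow(clone_sizes(assign_mlg(d)))
  expect_true(all(full == truth))
  expect_equal(stats::var(full), 0)
  # curve is nondecreasing in k on average
  means <- tapply(acc$n_mlg, acc$n_loci, mean)
  expect_true(all(diff(means) >= 0))

  # a locus that alone separates everything gives a flat curve
  n <- 8
  sep <- cbind(seq_len(n) * 2L - 1L, seq_len(n) * 2L,
               rep(1L, n), rep(1L, n))
  dsep <- make_clone_data(sep)
  # force the separating locus into every subset by making both loci separating
  sep2 <- cbind(sep[, 1:2], sep[, 1:2])
  dsep2 <- make_clone_data(sep2)
  acc2 <- genotype_accumulation(dsep2, n_permutations = 5, seed = 2)
  expect_true(all(acc2$n_mlg == n))
})
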