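# Fixture builders and independent brute-force oracles shared by the tests.

# Build a clone data tibble from a genotype matrix (n x 2L, alleles as
# integers, NA = missing) plus optional coordinates and patch ids.
make_clone_data <- function(geno, x = NULL, y = NULL, patch = "p1",
                            loci = NULL, ids = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  L <- ncol(geno) / 2L
  if (is.null(loci)) loci <- sprintf("loc%02d", seq_len(L))
  if (is.null(x)) x <- seq_len(n)
  if (is.null(y)) y <- rep(0, n)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(n))
  d <- tibble::tibble(
    sample_id = ids, x = x, y = y,
    patch_id = rep_len(patch, n)
  )
  gm <- matrix(as.integer(geno), nrow = n)
  colnames(gm) <- as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
  dplyr::bind_cols(d, tibble::as_tibble(gm))
}

# Random complete dataset: n units, L loci, k alleles per locus.
random_clone_data <- function(n, L = 8, k = 6, seed = 1) {
  set.seed(seed)
  geno <- matrix(sample.int(k, 2 * n * L, replace = TRUE), nrow = n)
  make_clone_data(geno, x = runif(n, 0, 10), y = runif(n, 0, 10))
}

# Multiset-intersection mismatch between two genotype rows (2L vector),
# computed the slow way with table().
oracle_mismatch <- function(g1, g2) {
  L <- length(g1) / 2L
  total <- 0L
  for (j in seq_len(L)) {
    a <- g1[c(2 * j - 1, 2 * j)]
    b <- g2[c(2 * j - 1, 2 * j)]
    shared <- 0L
    for (v in unique(a)) {
      shared <- shared + min(sum(a == v), sum(b == v))
    }
    total <- total + (2L - shared)
  }
  total
}

# Loiselle kinship for one pair by explicit double summation.
oracle_loiselle_pair <- function(data, freqs, i, j) {
  loci <- locus_names(data)
  g <- genotype_matrix(data)
  num <- 0
  den <- 0
  for (l in seq_along(loci)) {
    fl <- freqs[freqs$locus == loci[l], ]
    for (r in seq_len(nrow(fl))) {
      al <- fl$allele[r]; p <- fl$freq[r]
      xi <- sum(g[i, c(2 * l - 1, 2 * l)] == al) / 2
      xj <- sum(g[j, c(2 * l - 1, 2 * l)] == al) / 2
      num <- num + (xi - p) * (xj - p)
      den <- den + p * (1 - p)
    }
  }
  num / den + 1 / (nrow(data) - 1)
}

# Botstein PIC by direct double sum.
oracle_pic <- function(p) {
  s <- 1 - sum(p^2)
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      if (i < j) s <- s - 2 * p[i]^2 * p[j]^2
    }
  }
  s
}

# All-pairs nearest-neighbour S_mix.
oracle_smix <- function(x, y, ids, mlg) {
  n <- length(x)
  diff <- logical(n)
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    d[i] <- Inf
    cand <- which(d == min(d))
    j <- cand[order(ids[cand])][1]
    diff[i] <- mlg[j] != mlg[i]
  }
  mean(diff)
}

# Shoelace area, written independently of the package internals.
oracle_shoelace <- function(p) {
  n <- nrow(p)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2]
  }
  abs(s) / 2
}
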