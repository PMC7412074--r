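# Within-individual allele frequency matrix: rows = units, one column per
# (locus, allele) present in `freqs`; entries 0, 0.5 or 1.
allele_dosage_matrix <- function(data, freqs) {
  loci <- locus_names(data)
  g <- genotype_matrix(data)
  if (any(is.na(g))) stop("kinship requires complete genotypes")
  lk <- freq_lookup(freqs)
  cols <- list()
  for (j in seq_along(loci)) {
    pl <- lk[[loci[j]]]
    if (is.null(pl)) stop("no frequencies for locus ", loci[j])
    a <- g[, 2L * j - 1L]
    b <- g[, 2L * j]
    bad <- !(as.character(a) %in% names(pl)) | !(as.character(b) %in% names(pl))
    if (any(bad)) {
      stop("allele absent from frequencies at locus ", loci[j], ": ",
           paste(unique(c(a[bad], b[bad])), collapse = ", "))
    }
    x <- sapply(names(pl), function(al) {
      ((a == as.integer(al)) + (b == as.integer(al))) / 2
    })
    x <- matrix(x, nrow = nrow(g))
    colnames(x) <- paste0(loci[j], ":", names(pl))
    cols[[j]] <- x
  }
  do.call(cbind, cols)
}

#' Loiselle kinship coefficient matrix
#'
#' Pairwise kinship following Loiselle et al. (1995):
#' `F_ij = sum_l sum_a (x_ia - p_a)(x_ja - p_a) / sum_l sum_a p_a (1 - p_a)
#'  + 1 / (n - 1)`,
#' where `x_ia` is individual i's within-individual frequency of allele `a`
#' (0, 0.5 or 1) and `p_a` the reference allele frequency.  The formula
#' uses genotypes only; coordinates play no role here.
#'
#' @param data A clone data tibble (or genet representatives); complete
#'   genotypes required.
#' @param freqs Reference allele frequencies.
#' @return Symmetric numeric matrix with `sample_id` dimnames.
#' @export
loiselle_kinship <- function(data, freqs) {
  n <- nrow(data)
  if (n < 3L) stop("kinship needs at least 3 individuals")
  x <- allele_dosage_matrix(data, freqs)
  p <- freqs$freq[match(colnames(x), paste0(freqs$locus, ":", freqs$allele))]
  den <- sum(p * (1 - p))
  if (den <= 0) stop("all loci monomorphic: kinship undefined")
  xc <- sweep(x, 2L, p)
  f <- tcrossprod(xc) / den + 1 / (n - 1)
  dimnames(f) <- list(data$sample_id, data$sample_id)
  f
}

# Equal-pair-count distance classes over the upper-triangle pairs.
# Returns list(i, j, d, class, n_classes); class sizes differ by <= 1.
pair_classes <- function(x, y, n_classes) {
  n <- length(x)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
  m <- length(d)
  if (n_classes > m) stop("more distance classes than pairs")
  sizes <- rep(m %/% n_classes, n_classes)
  if (m %% n_classes > 0) sizes[seq_len(m %% n_classes)] <- sizes[seq_len(m %% n_classes)] + 1L
  cls <- integer(m)
  cls[order(d, method = "radix")] <- rep(seq_len(n_classes), times = sizes)
  list(i = i, j = j, d = d, class = cls, n_classes = n_classes)
}

#' Spatial genetic structure profile (distance-class kinship)
#'
#' Mean Loiselle kinship per distance class, with classes built to hold
#' equal numbers of pairs, at either the ramet level (every admitted unit)
#' or the genet level (one genotype per multilocus genotype, placed at the
#' arithmetic centroid of its ramets, with clone-censored reference
#' frequencies).  Significance per class is two-sided against the
#' permutation distribution obtained by randomly permuting spatial
#' locations among individuals; the envelope is the 2.5%/97.5% quantile
#' band of permuted class means.
#'
#' @param data A clone data tibble.
#' @param partition An `mlg_partition` from [assign_mlg()].
#' @param level `"ramet"` or `"genet"`.
#' @param n_classes Number of equal-count distance classes.
#' @param n_permutations Number of location permutations.
#' @param seed Optional integer seed.
#' @param freqs Reference allele frequencies; defaults to per-ramet
#'   frequencies at ramet level and clone-censored (per-genotype)
#'   frequencies at genet level.
#' @return A tibble of class `sgs_profile`: `level, class, d_max, d_mean,
#'   n_pairs, fij, lower, upper, p_value, significant`.
#' @export
sgs_profile <- function(data, partition, level = c("ramet", "genet"),
                        n_classes = 10, n_permutations = 1000,
                        seed = NULL, freqs = NULL) {
  level <- match.arg(level)
  joined <- dplyr::inner_join(
    data, as.data.frame(partition)[c("sample_id", "mlg_id")],
    by = "sample_id"
  ) %>% dplyr::filter(!is.na(.data$mlg_id))
  joined <- joined[complete_genotypes(joined), ]
  if (level == "genet") {
    cent <- joined %>%
      dplyr::group_by(.data$mlg_id) %>%
      dplyr::summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop")
    reps <- joined %>%
      dplyr::arrange(.data$sample_id) %>%
      dplyr::distinct(.data$mlg_id, .keep_all = TRUE) %>%
      dplyr::select(-"x", -"y") %>%
      dplyr::inner_join(cent, by = "mlg_id")
    units <- reps
    if (is.null(freqs)) freqs <- allele_freqs(joined, weighting = "per_genotype")
  } else {
    units <- joined
    if (is.null(freqs)) freqs <- allele_freqs(joined, weighting = "per_ramet")
  }
  f <- loiselle_kinship(units, freqs)
  pc <- pair_classes(units$x, units$y, n_classes)
  fij <- f[cbind(pc$i, pc$j)]
  cls <- factor(pc$class, levels = seq_len(n_classes))
  obs <- tapply(fij, cls, mean)
  n_pairs <- as.integer(table(cls))
  d_max <- tapply(pc$d, cls, max)
  d_mean <- tapply(pc$d, cls, mean)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(units)
  perm_means <- matrix(NA_real_, n_permutations, n_classes)
  for (b in seq_len(n_permutations)) {
    p <- sample.int(n)
    perm_means[b, ] <- tapply(f[cbind(p[pc$i], p[pc$j])], cls, mean)
  }
  lower <- apply(perm_means, 2L, stats::quantile, probs = 0.025)
  upper <- apply(perm_means, 2L, stats::quantile, probs = 0.975)
  p_val <- vapply(seq_len(n_classes), function(k) {
    ge <- sum(perm_means[, k] >= obs[k]) + 1
    le <- sum(perm_means[, k] <= obs[k]) + 1
    min(1, 2 * min(ge, le) / (n_permutations + 1))
  }, numeric(1))
  out <- tibble::tibble(
    level = level,
    class = seq_len(n_classes),
    d_max = as.numeric(d_max),
    d_mean = as.numeric(d_mean),
    n_pairs = n_pairs,
    fij = as.numeric(obs),
    lower = lower,
    upper = upper,
    p_value = p_val,
    significant = as.numeric(obs) < lower | as.numeric(obs) > upper
  )
  attr(out, "seed") <- seed
  attr(out, "n_permutations") <- n_permutations
  class(out) <- c("sgs_profile", class(out))
  out
}
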