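#' Probability of a multilocus genotype (Pgen)
#'
#' Probability of drawing each unit's multilocus genotype from reference
#' allele frequencies, as a product over loci of the single-locus genotype
#' probabilities.  Under Hardy-Weinberg equilibrium (`fis = 0`) these are
#' `p^2` for homozygotes and `2pq` for heterozygotes; with a departure
#' `F_IS` they become `p^2 + p(1-p)F` and `2pq(1-F)`.
#'
#' @param data A clone data tibble (complete genotypes required).
#' @param freqs Allele frequencies, e.g. from [round_robin_freqs()].
#' @param fis Inbreeding coefficient: a single number applied to all loci,
#'   or a named vector with one entry per locus.
#' @return Numeric vector of probabilities, one per row of `data`.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   sample_id = "s", x = 0, y = 0, patch_id = "p",
#'   locA_1 = 1L, locA_2 = 1L
#' )
#' f <- tibble::tibble(locus = "locA", allele = 1:2, freq = 0.5, n_obs = 4L)
#' pgen(d, f) # 0.25
pgen <- function(data, freqs, fis = 0) {
  loci <- locus_names(data)
  g <- genotype_matrix(data)
  if (any(is.na(g))) stop("pgen requires complete genotypes")
  lk <- freq_lookup(freqs)
  if (length(fis) == 1L && is.null(names(fis))) {
    fis <- stats::setNames(rep(fis, length(loci)), loci)
  }
  if (!all(loci %in% names(fis))) stop("fis must cover every locus")
  out <- rep(1, nrow(data))
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
    p <- pl[as.character(a)]
    q <- pl[as.character(b)]
    f <- fis[[loci[j]]]
    out <- out * ifelse(a == b, p^2 + p * (1 - p) * f, 2 * p * q * (1 - f))
  }
  unname(out)
}

#' Probability of clonal identity (Psex)
#'
#' Probability that a multilocus genotype observed `n` times among `N`
#' sampling units arose at least `n` times from independent sexual
#' reproductive events, given its drawing probability `p_gen`:
#' `Psex = 1 - sum_{l=0}^{n-1} C(N,l) p^l (1-p)^(N-l)`.  Small values mean
#' the repeats are almost certainly clonemates.
#'
#' @param p_gen Genotype probability (e.g. from [pgen()]); vectorised.
#' @param n_samples Total number of sampling units `N`.
#' @param n_copies Observed number of copies `n` (vectorised with `p_gen`).
#' @return Numeric vector of probabilities.
#' @export
psex <- function(p_gen, n_samples, n_copies) {
  if (any(n_copies < 1) || any(n_copies > n_samples)) {
    stop("n_copies must lie in [1, n_samples]")
  }
  if (any(p_gen < 0 | p_gen > 1)) stop("p_gen must lie in [0, 1]")
  stats::pbinom(n_copies - 1, n_samples, p_gen, lower.tail = FALSE)
}

# Per-locus FIS = (He - Ho) / He on one representative per MLG
# (clone-censored); monomorphic loci give NA.
estimate_fis <- function(data, partition) {
  stats <- locus_stats(data, partition, include_mean = FALSE)
  fis <- stats::setNames(stats$fis, stats$locus)
  fis[is.na(fis)] <- 0
  fis
}

#' Clone confidence table (Pgen / Psex families)
#'
#' For every multilocus genotype observed at least twice, computes Pgen and
#' Psex under HWE and under the clone-censored estimate of `F_IS`
#' (`Pgen(FIS)`, `Psex(FIS)`).  Allele frequencies default to the
#' round-robin clone-censored estimates, and `F_IS` defaults to per-locus
#' values estimated from one representative per genotype.
#'
#' @param data A clone data tibble.
#' @param partition An `mlg_partition` from [assign_mlg()].
#' @param freqs Allele frequencies (default [round_robin_freqs()]).
#' @param fis Per-locus or scalar `F_IS` (default estimated from the
#'   clone-censored data).
#' @return A tibble `mlg_id, n_g, pgen, pgen_fis, psex, psex_fis`, one row
#'   per repeated genotype.
#' @export
clone_confidence <- function(data, partition, freqs = NULL, fis = NULL) {
  if (is.null(freqs)) freqs <- round_robin_freqs(data)
  if (is.null(fis)) fis <- estimate_fis(data, partition)
  joined <- dplyr::inner_join(
    data, as.data.frame(partition)[c("sample_id", "mlg_id", "n_g")],
    by = "sample_id"
  ) %>%
    dplyr::filter(!is.na(.data$mlg_id), .data$n_g >= 2L) %>%
    dplyr::arrange(.data$mlg_id, .data$sample_id) %>%
    dplyr::distinct(.data$mlg_id, .keep_all = TRUE)
  n_total <- sum(!is.na(partition$mlg_id))
  if (nrow(joined) == 0L) {
    return(tibble::tibble(
      mlg_id = character(), n_g = integer(), pgen = numeric(),
      pgen_fis = numeric(), psex = numeric(), psex_fis = numeric()
    ))
  }
  pg <- pgen(joined, freqs, fis = 0)
  pgf <- pgen(joined, freqs, fis = fis)
  tibble::tibble(
    mlg_id = joined$mlg_id,
    n_g = joined$n_g,
    pgen = pg,
    pgen_fis = pgf,
    psex = psex(pg, n_total, joined$n_g),
    psex_fis = psex(pgf, n_total, joined$n_g)
  )
}

#' Genotype accumulation curve
#'
#' Measures the discriminatory power of the marker set: for each subset size
#' `k < L`, loci are repeatedly drawn without replacement and the number of
#' distinct multilocus genotypes resolvable with those `k` loci is counted;
#' at `k = L` the full-data genotype count is returned once per replicate
#' (zero variance).  A curve that plateaus below `L` indicates the markers
#' suffice to detect all genotypes.
#'
#' @param data A clone data tibble (units with missing calls are excluded).
#' @param n_permutations Locus subsets drawn per subset size.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble `n_loci, perm, n_mlg` of class `genotype_accumulation`.
#' @export
genotype_accumulation <- function(data, n_permutations = 100, seed = NULL) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  loci <- locus_names(data)
  L <- length(loci)
  if (L < 2L) stop("need at least 2 loci")
  if (!is.null(seed)) set.seed(seed)
  g <- genotype_matrix(data)
  g <- g[rowSums(is.na(g)) == 0L, , drop = FALSE]
  count_mlg <- function(which_loci) {
    cols <- as.vector(rbind(2L * which_loci - 1L, 2L * which_loci))
    length(unique(apply(g[, cols, drop = FALSE], 1L, paste, collapse = "/")))
  }
  out <- tidyr::expand_grid(n_loci = seq_len(L), perm = seq_len(n_permutations))
  full <- count_mlg(seq_len(L))
  out$n_mlg <- purrr::map2_int(out$n_loci, out$perm, function(k, p) {
    if (k == L) return(full)
    count_mlg(sort(sample.int(L, k)))
  })
  attr(out, "seed") <- seed
  class(out) <- c("genotype_accumulation", class(out))
  out
}
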