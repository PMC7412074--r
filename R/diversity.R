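#' Per-locus diversity statistics on clone-censored data
#'
#' Statistics are computed on one representative ramet per multilocus
#' genotype (the first by sorted `sample_id`; clonemates are identical at
#' threshold 0, so the choice is immaterial).  Per locus: number of alleles
#' `na`, observed heterozygosity `ho` (fraction of heterozygous genotypes),
#' expected heterozygosity `he = 1 - sum(p^2)`, Botstein's polymorphic
#' information content `pic = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`, and
#' the inbreeding coefficient `fis = (he - ho) / he` (undefined and reported
#' `NA`, with a warning, for monomorphic loci).
#'
#' @param data A clone data tibble.
#' @param partition An `mlg_partition` from [assign_mlg()].
#' @param include_mean Append a `"Mean"` row with per-column means (the
#'   conventional bottom row of a per-locus table)?
#' @return A tibble `locus, n_genotypes, na, ho, he, pic, fis`.
#' @export
locus_stats <- function(data, partition, include_mean = TRUE) {
  reps <- dplyr::inner_join(
    data, as.data.frame(partition)[c("sample_id", "mlg_id")],
    by = "sample_id"
  ) %>%
    dplyr::filter(!is.na(.data$mlg_id)) %>%
    dplyr::arrange(.data$sample_id) %>%
    dplyr::distinct(.data$mlg_id, .keep_all = TRUE)
  if (dplyr::n_distinct(reps$mlg_id) < 2L) stop("need at least 2 genotypes")
  loci <- locus_names(data)
  g <- genotype_matrix(reps)
  res <- purrr::map_dfr(seq_along(loci), function(j) {
    a <- g[, 2L * j - 1L]
    b <- g[, 2L * j]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    p <- as.numeric(table(c(a, b))) / (2 * length(a))
    ho <- mean(a != b)
    he <- 1 - sum(p^2)
    pic <- 1 - sum(p^2) - (sum(outer(p^2, p^2))
                           - sum(p^4)) # 2 * sum_{i<j} p_i^2 p_j^2
    fis <- if (he > 0) (he - ho) / he else NA_real_
    tibble::tibble(
      locus = loci[j], n_genotypes = length(a),
      na = length(p), ho = ho, he = he, pic = pic, fis = fis
    )
  })
  if (any(is.na(res$fis))) {
    warning("monomorphic locus: FIS undefined for ",
            paste(res$locus[is.na(res$fis)], collapse = ", "))
  }
  if (include_mean) {
    res <- dplyr::bind_rows(res, dplyr::summarise(
      res,
      locus = "Mean",
      dplyr::across(c("n_genotypes", "na"), ~ mean(.x)),
      dplyr::across(c("ho", "he", "pic", "fis"), ~ mean(.x, na.rm = TRUE))
    ))
  }
  res
}

#' Genotypic richness
#'
#' Dorken-Eckert genotypic richness `R = (G - 1) / (N - 1)` for `G` distinct
#' genotypes (genets) among `N` sampling units: 0 when all units belong to
#' one genet, 1 when every unit is genetically unique.
#'
#' @param n_units Number of sampling units `N` (>= 2).
#' @param n_genotypes Number of distinct multilocus genotypes `G`.
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' genotypic_richness(687, 241) # 0.35
genotypic_richness <- function(n_units, n_genotypes) {
  if (n_units < 2) stop("genotypic richness needs N >= 2")
  if (n_genotypes < 1 || n_genotypes > n_units) stop("G must lie in [1, N]")
  (n_genotypes - 1) / (n_units - 1)
}

#' Shannon-Wiener equitability of clone sizes
#'
#' `E_H = (-sum p_i log p_i) / log S` where `p_i` is the share of ramets in
#' genet `i` and `S` the number of genets: 0 when all ramets belong to one
#' genet (defined so also at `S = 1`), 1 under complete evenness.
#'
#' @param clone_sizes Positive integer ramet counts per genet.
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' equitability(c(5, 5)) # 1
equitability <- function(clone_sizes) {
  if (length(clone_sizes) < 1L || any(clone_sizes <= 0)) {
    stop("clone sizes must be positive")
  }
  s <- length(clone_sizes)
  if (s == 1L) return(0)
  p <- clone_sizes / sum(clone_sizes)
  h <- -sum(p * log(p))
  h / log(s)
}

#' Slope of the Pareto clone-size distribution
#'
#' Fits `log N(>= X) = a - beta log X` by ordinary least squares over the
#' distinct observed clone sizes `X`, where `N(>= X)` is the number of
#' genets of size at least `X`, and returns `beta`.  Shallow slopes indicate
#' dominance of a few large clones; steep slopes indicate many small ones.
#'
#' @param clone_sizes Positive integer ramet counts per genet, with at
#'   least two distinct values.
#' @param drop_largest Drop the largest size class before fitting (an
#'   occasionally used robustification)?
#' @return The fitted exponent `beta` (positive for decreasing tails).
#' @export
pareto_slope <- function(clone_sizes, drop_largest = FALSE) {
  if (any(clone_sizes <= 0)) stop("clone sizes must be positive")
  xs <- sort(unique(clone_sizes))
  if (drop_largest && length(xs) > 2L) xs <- xs[-length(xs)]
  if (length(xs) < 2L) stop("Pareto slope needs at least two distinct clone sizes")
  n_ge <- vapply(xs, function(x) sum(clone_sizes >= x), numeric(1))
  fit <- stats::lm(log(n_ge) ~ log(xs))
  -unname(stats::coef(fit)[2L])
}

#' Clonal subrange
#'
#' The maximum Euclidean distance between two ramets of the same genet: the
#' spatial extent over which clonal spread is observed.
#'
#' @param data A clone data tibble.
#' @param partition An `mlg_partition` from [assign_mlg()].
#' @return Distance in metres; 0 (with a warning) when no genet is sampled
#'   more than once.
#' @export
clonal_subrange <- function(data, partition) {
  joined <- dplyr::inner_join(
    data[c("sample_id", "x", "y")],
    as.data.frame(partition)[c("sample_id", "mlg_id", "n_g")],
    by = "sample_id"
  ) %>% dplyr::filter(!is.na(.data$mlg_id), .data$n_g >= 2L)
  if (nrow(joined) == 0L) {
    warning("no repeated genotype: clonal subrange is 0")
    return(0)
  }
  max(vapply(split(joined, joined$mlg_id), function(d) {
    max(stats::dist(cbind(d$x, d$y)))
  }, numeric(1)))
}

#' Population-level clonal diversity summary
#'
#' @param data A clone data tibble.
#' @param partition An `mlg_partition` from [assign_mlg()].
#' @return A one-row tibble: `n` (admitted units), `n_mlg`, `max_ng`,
#'   `richness`, `pareto_beta`, `equitability`, `clonal_subrange`.
#' @export
diversity_stats <- function(data, partition) {
  sz <- clone_sizes(partition)
  n <- sum(sz$n_g)
  beta <- tryCatch(pareto_slope(sz$n_g), error = function(e) NA_real_)
  subr <- withCallingHandlers(
    clonal_subrange(data, partition),
    warning = function(w) invokeRestart("muffleWarning")
  )
  tibble::tibble(
    n = n,
    n_mlg = nrow(sz),
    max_ng = max(sz$n_g),
    richness = genotypic_richness(n, nrow(sz)),
    pareto_beta = beta,
    equitability = equitability(sz$n_g),
    clonal_subrange = subr
  )
}
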