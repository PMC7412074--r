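#' Pairwise allelic mismatch matrix
#'
#' For every pair of ramets, the number of allele-level differences summed
#' over loci: at each locus the contribution is `2 - |intersection|` of the
#' two allele pairs compared as multisets, so identical genotypes score 0,
#' a shared single allele scores 1, and disjoint genotypes score 2.  Values
#' range from 0 to twice the number of loci.
#'
#' Only ramets with complete genotypes are admitted (see
#' [complete_genotypes()]); with `incomplete = "pairwise"` all ramets are
#' kept and each pair is compared over its mutually non-missing loci.
#'
#' @param data A clone data tibble.
#' @param incomplete `"exclude"` (default) drops units with missing calls;
#'   `"pairwise"` keeps them and compares mutually scored loci only.
#' @return Symmetric integer matrix with `sample_id` dimnames and zero
#'   diagonal.
#' @export
mismatch_matrix <- function(data, incomplete = c("exclude", "pairwise")) {
  incomplete <- match.arg(incomplete)
  g <- genotype_matrix(data)
  if (incomplete == "exclude") {
    keep <- rowSums(is.na(g)) == 0L
    if (!all(keep)) {
      warning(sum(!keep), " unit(s) with missing calls excluded from clone discrimination")
    }
    g <- g[keep, , drop = FALSE]
  }
  n <- nrow(g)
  L <- ncol(g) / 2L
  d <- matrix(0L, n, n, dimnames = list(rownames(g), rownames(g)))
  for (j in seq_len(L)) {
    a1 <- g[, 2L * j - 1L]
    a2 <- g[, 2L * j]
    # alleles are sorted within locus by genotype_matrix()
    A1 <- matrix(a1, n, n)        # rows: unit i
    A2 <- matrix(a2, n, n)
    B1 <- t(A1)                   # cols: unit k
    B2 <- t(A2)
    hom <- A1 == A2
    shared <- ifelse(hom,
      (B1 == A1) + (B2 == A1),
      (A1 == B1 | A1 == B2) + (A2 == B1 | A2 == B2)
    )
    contrib <- 2L - shared
    contrib[is.na(contrib)] <- 0L  # mutually missing loci contribute 0
    d <- d + contrib
  }
  storage.mode(d) <- "integer"
  diag(d) <- 0L
  d
}

#' Histogram of pairwise allelic mismatches
#'
#' Tabulates the upper triangle of a mismatch matrix over the mismatch
#' classes 0 to twice the locus count.  Used to look for the gap between
#' clonemate pairs (putative
#' somatic mutations, low mismatch) and pairs of distinct genets that
#' motivates a multilocus-lineage threshold.
#'
#' @param m A mismatch matrix from [mismatch_matrix()].
#' @param max_mismatch Upper bound of the histogram support (defaults to the
#'   maximum observed).
#' @return A tibble with columns `mismatches`, `n_pairs`.
#' @export
mismatch_histogram <- function(m, max_mismatch = NULL) {
  if (nrow(m) < 2L) stop("need at least two units")
  v <- m[upper.tri(m)]
  if (is.null(max_mismatch)) max_mismatch <- max(v)
  tibble::tibble(
    mismatches = 0:max_mismatch,
    n_pairs = as.integer(tabulate(factor(v, levels = 0:max_mismatch)))
  )
}

# Deterministic union-find over n elements.
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      a <- find(edges[r, 1L]); b <- find(edges[r, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Assign ramets to multilocus genotypes or lineages
#'
#' Groups units by single linkage over the graph of pairs whose allelic
#' mismatch count is at most `threshold`.  At `threshold = 0` this is exact
#' multilocus genotype (MLG) identity; positive thresholds merge MLGs that
#' differ by putative somatic mutations or scoring errors into multilocus
#' lineages (MLLs).  Higher thresholds can only merge groups, never split
#' them.
#'
#' Group ids are assigned by first appearance after sorting admitted units
#' by `sample_id`, so the labelling is independent of row order and of
#' coordinates.  Units with missing calls are excluded (with a warning) and
#' given `NA` ids unless `incomplete = "pairwise"`.
#'
#' @param data A clone data tibble.
#' @param threshold Non-negative integer mismatch threshold (must be below
#'   `2 * n_loci`).
#' @inheritParams mismatch_matrix
#' @return A tibble of class `mlg_partition` with columns `sample_id`,
#'   `mlg_id`, `n_g` (clone size of the unit's group); the threshold is kept
#'   in attribute `threshold`.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   sample_id = c("a", "b", "c"), x = c(0, 1, 2), y = 0, patch_id = "p",
#'   locA_1 = c(1L, 1L, 2L), locA_2 = c(1L, 1L, 3L),
#'   locB_1 = c(5L, 5L, 5L), locB_2 = c(6L, 6L, 6L)
#' )
#' assign_mlg(d)
assign_mlg <- function(data, threshold = 0L, incomplete = c("exclude", "pairwise")) {
  incomplete <- match.arg(incomplete)
  loci <- locus_names(data)
  if (threshold < 0 || threshold >= 2L * length(loci)) {
    stop("threshold must be in [0, 2 * n_loci)")
  }
  m <- withCallingHandlers(
    mismatch_matrix(data, incomplete = incomplete),
    warning = function(w) invokeRestart("muffleWarning")
  )
  admitted <- rownames(m)
  dropped <- setdiff(data$sample_id, admitted)
  if (length(dropped) > 0) {
    warning(length(dropped), " unit(s) with missing calls excluded from clone discrimination")
  }
  ord <- order(admitted)
  m <- m[ord, ord, drop = FALSE]
  ids <- admitted[ord]
  n <- length(ids)
  hit <- which(m <= threshold & upper.tri(m), arr.ind = TRUE)
  comp <- uf_components(n, hit)
  first_seen <- match(unique(comp), comp)
  grp <- match(comp, comp[sort(first_seen)])
  mlg <- sprintf("MLG%03d", grp)
  sizes <- table(mlg)
  out <- tibble::tibble(sample_id = ids, mlg_id = mlg,
                        n_g = as.integer(sizes[mlg]))
  if (length(dropped) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      sample_id = dropped, mlg_id = NA_character_, n_g = NA_integer_
    ))
  }
  out <- out[match(data$sample_id, out$sample_id), ]
  attr(out, "threshold") <- as.integer(threshold)
  class(out) <- c("mlg_partition", class(out))
  out
}

#' Clone sizes of a partition
#'
#' @param partition An `mlg_partition` from [assign_mlg()].
#' @return A tibble `mlg_id`, `n_g`, one row per group, sorted by id.
#' @export
clone_sizes <- function(partition) {
  partition %>%
    dplyr::filter(!is.na(.data$mlg_id)) %>%
    dplyr::distinct(.data$mlg_id, .data$n_g) %>%
    dplyr::arrange(.data$mlg_id)
}

#' @export
print.mlg_partition <- function(x, ...) {
  sz <- clone_sizes(x)
  cat("Multilocus genotype partition (threshold ",
      attr(x, "threshold"), ")\n", sep = "")
  cat("  ", sum(!is.na(x$mlg_id)), " units in ", nrow(sz),
      " groups; max clone size ", max(sz$n_g), "\n", sep = "")
  NextMethod()
}
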