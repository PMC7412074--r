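#' Allele frequencies from a clone data table
#'
#' Relative allele frequencies per locus, computed either over every sampled
#' ramet (`per_ramet`: each non-missing call contributes two allele
#' observations) or over distinct multilocus genotypes (`per_genotype`: one
#' observation per distinct genotype, i.e. clone-censored).
#'
#' @param data A clone data tibble.
#' @param weighting `"per_ramet"` or `"per_genotype"`.
#' @return A tibble with columns `locus`, `allele`, `freq`, `n_obs` (number
#'   of allele observations at the locus).  Frequencies sum to 1 per locus.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   sample_id = c("s1", "s2"), x = 0, y = 0, patch_id = "p",
#'   locA_1 = c(1L, 1L), locA_2 = c(1L, 2L)
#' )
#' allele_freqs(d) # A: 0.75, B: 0.25
allele_freqs <- function(data, weighting = c("per_ramet", "per_genotype")) {
  weighting <- match.arg(weighting)
  loci <- locus_names(data)
  g <- genotype_matrix(data)
  if (weighting == "per_genotype") {
    cg <- complete_genotypes(data)
    key <- apply(g[cg, , drop = FALSE], 1L, paste, collapse = "/")
    g <- g[cg, , drop = FALSE][!duplicated(key), , drop = FALSE]
  }
  freqs_from_matrix(g, loci)
}

freqs_from_matrix <- function(g, loci) {
  res <- purrr::map_dfr(seq_along(loci), function(j) {
    calls <- c(g[, 2L * j - 1L], g[, 2L * j])
    calls <- calls[!is.na(calls)]
    if (length(calls) == 0L) {
      stop("locus ", loci[j], " has no non-missing calls")
    }
    tab <- table(calls)
    tibble::tibble(
      locus = loci[j],
      allele = as.integer(names(tab)),
      freq = as.numeric(tab) / length(calls),
      n_obs = length(calls)
    )
  })
  res
}

#' Round-robin (clone-censored) allele frequencies
#'
#' For each locus in turn, multilocus genotypes are identified using all the
#' *other* loci; allele frequencies at the focal locus are then computed with
#' one observation per such genotype.  This removes the upward bias that
#' clonal replicates would otherwise impose on the frequency of the alleles
#' carried by large clones, following the round-robin scheme of Parks and
#' Werth.
#'
#' Units missing any call at the non-focal loci, or at the focal locus, are
#' dropped for that locus only.
#'
#' @param data A clone data tibble with at least two loci.
#' @return A tibble in the same shape as [allele_freqs()].
#' @export
round_robin_freqs <- function(data) {
  loci <- locus_names(data)
  if (length(loci) < 2L) stop("round-robin frequencies need at least 2 loci")
  g <- genotype_matrix(data)
  ord <- order(data$sample_id)
  g <- g[ord, , drop = FALSE]
  purrr::map_dfr(seq_along(loci), function(j) {
    focal <- c(2L * j - 1L, 2L * j)
    others <- setdiff(seq_len(2L * length(loci)), focal)
    ok <- rowSums(is.na(g[, others, drop = FALSE])) == 0L &
      rowSums(is.na(g[, focal, drop = FALSE])) == 0L
    sub <- g[ok, , drop = FALSE]
    if (nrow(sub) == 0L) stop("locus ", loci[j], " has no usable genotypes")
    key <- apply(sub[, others, drop = FALSE], 1L, paste, collapse = "/")
    rep_rows <- sub[!duplicated(key), focal, drop = FALSE]
    calls <- as.vector(rep_rows)
    tab <- table(calls)
    tibble::tibble(
      locus = loci[j],
      allele = as.integer(names(tab)),
      freq = as.numeric(tab) / length(calls),
      n_obs = length(calls)
    )
  })
}

# Fast lookup structure: named list locus -> named numeric vector of freqs.
freq_lookup <- function(freqs) {
  split(stats::setNames(freqs$freq, freqs$allele), freqs$locus)
}
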