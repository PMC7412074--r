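# Nearest-neighbour index per unit, ties broken by smallest sample_id.
nearest_neighbours <- function(x, y, sample_id) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  rank_id <- rank(sample_id, ties.method = "first")
  vapply(seq_len(nrow(d)), function(i) {
    cand <- which(d[i, ] == min(d[i, ]))
    cand[which.min(rank_id[cand])]
  }, integer(1))
}

#' Spatial aggregation index of clonemates (Ac)
#'
#' Compares the observed probability that a unit's nearest neighbour is a
#' clonemate (`Psp`) with the probability that two random distinct units
#' are clonemates (`Psg = sum n_g (n_g - 1) / (N (N - 1))`), normalised to
#' `Ac = (Psp - Psg) / (1 - Psg)` so that 0 means random nearest-neighbour
#' clone sharing and 1 means every nearest neighbour is a clonemate.
#' Significance is assessed by permuting coordinates among units
#' (equivalently, genotype labels), with
#' `p = (#{Ac_perm >= Ac_obs} + 1) / (n_permutations + 1)`.
#'
#' @param data A clone data tibble.
#' @param partition An `mlg_partition` from [assign_mlg()].
#' @param n_permutations Number of random permutations.
#' @param seed Optional integer seed.
#' @return An object of class `clone_aggregation`: a list with `ac`, `psp`,
#'   `psg`, `p_value`, `n_permutations`, `n`, `seed`.  Has [generics::tidy()]
#'   and [generics::glance()] methods.
#' @export
aggregation_index <- function(data, partition, n_permutations = 1000, seed = NULL) {
  joined <- dplyr::inner_join(
    data[c("sample_id", "x", "y")],
    as.data.frame(partition)[c("sample_id", "mlg_id", "n_g")],
    by = "sample_id"
  ) %>% dplyr::filter(!is.na(.data$mlg_id))
  n <- nrow(joined)
  if (n < 3L) stop("aggregation index needs at least 3 admitted units")
  sz <- table(joined$mlg_id)
  psg <- sum(sz * (sz - 1)) / (n * (n - 1))
  if (psg >= 1) stop("all units belong to one clone: aggregation index undefined")
  if (psg == 0) {
    # no repeated genotype: nothing to aggregate
    out <- list(ac = 0, psp = 0, psg = 0, p_value = 1,
                n_permutations = n_permutations, n = n, seed = seed)
    class(out) <- "clone_aggregation"
    return(out)
  }
  nn <- nearest_neighbours(joined$x, joined$y, joined$sample_id)
  mlg <- joined$mlg_id
  ac_of <- function(lab) {
    psp <- mean(lab[nn] == lab)
    (psp - psg) / (1 - psg)
  }
  obs_psp <- mean(mlg[nn] == mlg)
  obs <- (obs_psp - psg) / (1 - psg)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_permutations), function(i) ac_of(sample(mlg)), numeric(1))
  p <- (sum(perm >= obs) + 1) / (n_permutations + 1)
  out <- list(ac = obs, psp = obs_psp, psg = psg, p_value = p,
              n_permutations = n_permutations, n = n, seed = seed)
  class(out) <- "clone_aggregation"
  out
}

#' @export
print.clone_aggregation <- function(x, ...) {
  cat("Clonemate aggregation index\n")
  cat(sprintf("  Ac = %.3f (Psp = %.3f, Psg = %.3f), n = %d\n",
              x$ac, x$psp, x$psg, x$n))
  cat(sprintf("  permutation p = %.4g (%d permutations)\n",
              x$p_value, x$n_permutations))
  invisible(x)
}

#' @export
tidy.clone_aggregation <- function(x, ...) {
  tibble::tibble(
    term = "Ac", estimate = x$ac, p.value = x$p_value
  )
}

#' @export
glance.clone_aggregation <- function(x, ...) {
  tibble::tibble(
    ac = x$ac, psp = x$psp, psg = x$psg, p.value = x$p_value,
    n = x$n, n_permutations = x$n_permutations
  )
}
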