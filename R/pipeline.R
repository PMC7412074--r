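#' Run the full clonal-structure analysis
#'
#' Orchestrates every stage on one dataset: multilocus genotype assignment
#' (with the chosen mismatch threshold), clone confidence (Pgen/Psex on
#' round-robin frequencies), clone-censored per-locus statistics,
#' population-level clonal diversity, clonemate aggregation, Loiselle
#' kinship profiles at ramet and genet level, genet footprints with overlap
#' accounting, and per-patch indices with their regressions on patch area
#' when outlines are available.  Every stochastic step derives its seed
#' from `seed`, and all seeds are recorded in the result.
#'
#' @param data A clone data tibble (see [read_clone_data()]).
#' @param outlines Optional patch outline vertices (`patch_id, x, y`) or a
#'   precomputed `patch_id, a_p` table.
#' @param threshold Mismatch threshold for multilocus lineage merging
#'   (0 = exact genotypes).
#' @param n_permutations Permutations for the aggregation and kinship
#'   tests.
#' @param n_classes Distance classes for the kinship profiles.
#' @param seed Integer seed.
#' @param surface Also compute the local genotypic richness surface?
#' @param out_dir Optional directory: per-stage CSV artifacts and a JSON
#'   summary are written there.
#' @return A list of class `clone_analysis` with one element per stage.
#' @export
run_clone_analysis <- function(data, outlines = NULL, threshold = 0L,
                               n_permutations = 1000, n_classes = 10,
                               seed = 1L, surface = FALSE, out_dir = NULL) {
  validate_clone_data(data)
  seeds <- seed + 0:3
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  partition <- stage("identify", assign_mlg(data, threshold = threshold))
  confidence <- stage("confidence", clone_confidence(data, partition))
  lstats <- stage("diversity", locus_stats(data, partition))
  diversity <- stage("diversity", diversity_stats(data, partition))
  aggregation <- stage("sgs", aggregation_index(
    data, partition, n_permutations = n_permutations, seed = seeds[1L]
  ))
  sgs_ramet <- stage("sgs", sgs_profile(
    data, partition, level = "ramet", n_classes = n_classes,
    n_permutations = n_permutations, seed = seeds[2L]
  ))
  sgs_genet <- stage("sgs", sgs_profile(
    data, partition, level = "genet", n_classes = n_classes,
    n_permutations = n_permutations, seed = seeds[3L]
  ))
  footprints <- stage("geometry", genet_footprints(data, partition))
  overlap <- stage("geometry", overlap_report(footprints))
  pstats <- stage("patch", suppressWarnings(
    patch_stats(data, partition, outlines = outlines)
  ))
  regressions <- if (sum(!is.na(pstats$a_p)) >= 3L) {
    stage("patch", patch_regressions(pstats))
  } else NULL
  rich <- if (surface) {
    stage("patch", richness_surface(data, partition))
  } else NULL
  out <- list(
    partition = partition, confidence = confidence,
    locus_stats = lstats, diversity = diversity,
    aggregation = aggregation, sgs_ramet = sgs_ramet, sgs_genet = sgs_genet,
    footprints = footprints, overlap = overlap,
    patch_stats = pstats, regressions = regressions,
    surface = rich,
    threshold = threshold, seed = seed, seeds = seeds
  )
  class(out) <- "clone_analysis"
  if (!is.null(out_dir)) write_clone_analysis(out, out_dir)
  out
}

#' @export
print.clone_analysis <- function(x, ...) {
  d <- x$diversity
  cat("Clonal structure analysis\n")
  cat(sprintf("  %d units -> %d multilocus genotypes (threshold %d); max clone size %d\n",
              d$n, d$n_mlg, x$threshold, d$max_ng))
  cat(sprintf("  richness R = %.2f, Pareto beta = %.2f, E_H = %.2f, subrange = %.2f m\n",
              d$richness, d$pareto_beta, d$equitability, d$clonal_subrange))
  cat(sprintf("  aggregation Ac = %.2f (p = %s)\n",
              x$aggregation$ac, format_pval(x$aggregation$p_value)))
  cat(sprintf("  footprint overlap: %.2f%% of the union covered by >=2 genets\n",
              x$overlap$percent_overlap))
  if (!is.null(x$regressions)) {
    cat("  patch regressions on area:",
        paste(sprintf("%s r = %.3f", x$regressions$response, x$regressions$r),
              collapse = "; "), "\n")
  }
  if (nrow(x$confidence) > 0) {
    cat(sprintf("  max Psex(FIS) among repeated genotypes: %.2g\n",
                max(x$confidence$psex_fis)))
  }
  invisible(x)
}

#' Headline summary of a clone analysis
#'
#' @param x A `clone_analysis` from [run_clone_analysis()].
#' @param ... Unused.
#' @return A one-row tibble with the headline statistics.
#' @export
glance.clone_analysis <- function(x, ...) {
  dplyr::bind_cols(
    x$diversity,
    tibble::tibble(
      ac = x$aggregation$ac,
      ac_p_value = x$aggregation$p_value,
      percent_overlap = x$overlap$percent_overlap,
      max_multiplicity = x$overlap$max_multiplicity
    )
  )
}

write_clone_analysis <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    readr::write_csv(as.data.frame(df), file.path(out_dir, paste0(name, ".csv")),
                     progress = FALSE)
  }
  w(as.data.frame(x$partition), "mlg_partition")
  w(x$confidence, "clone_confidence")
  w(x$locus_stats, "locus_stats")
  w(x$diversity, "diversity_stats")
  w(tibble::as_tibble(x$sgs_ramet), "sgs_ramet")
  w(tibble::as_tibble(x$sgs_genet), "sgs_genet")
  w(dplyr::select(tibble::as_tibble(x$footprints), -"polygon"), "genet_footprints")
  w(x$overlap$pairs, "overlap_pairs")
  w(x$patch_stats, "patch_stats")
  if (!is.null(x$regressions)) w(x$regressions, "patch_regressions")
  writeLines(
    footprints_wkt(x$footprints),
    file.path(out_dir, "genet_footprints.wkt")
  )
  summary <- c(
    as.list(glance.clone_analysis(x)),
    list(threshold = x$threshold, seed = x$seed, seeds = x$seeds)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' WKT export of genet footprints
#'
#' @param footprints A `genet_footprints` tibble.
#' @return Character vector, one `POLYGON` per footprint (with its
#'   `mlg_id` as a prefix comment-free CSV-style field).
#' @export
footprints_wkt <- function(footprints) {
  vapply(seq_len(nrow(footprints)), function(k) {
    poly <- footprints$polygon[[k]]
    if (is.null(poly)) return(sprintf("%s\tPOLYGON EMPTY", footprints$mlg_id[k]))
    ring <- rbind(poly, poly[1L, , drop = FALSE])
    coords <- paste(sprintf("%.6f %.6f", ring[, 1L], ring[, 2L]), collapse = ", ")
    sprintf("%s\tPOLYGON ((%s))", footprints$mlg_id[k], coords)
  }, character(1))
}
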