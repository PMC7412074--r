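#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

reserved_cols <- c("sample_id", "x", "y", "patch_id")

#' Locus names of a clone data table
#'
#' A clone data table holds one row per sampled ramet with columns
#' `sample_id`, `x`, `y`, `patch_id` followed by two integer allele columns
#' per microsatellite locus, named `<locus>_1` and `<locus>_2`.  Missing
#' allele calls are `NA`.
#'
#' @param data A clone data tibble.
#' @return Character vector of locus names, in column order.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   sample_id = "s1", x = 0, y = 0, patch_id = "p1",
#'   locA_1 = 100L, locA_2 = 102L, locB_1 = 90L, locB_2 = 90L
#' )
#' locus_names(d)
locus_names <- function(data) {
  nm <- setdiff(names(data), reserved_cols)
  first <- nm[grepl("_1$", nm)]
  stems <- sub("_1$", "", first)
  missing2 <- stems[!paste0(stems, "_2") %in% nm]
  if (length(missing2) > 0) {
    stop("loci without a second allele column: ", paste(missing2, collapse = ", "))
  }
  stems
}

locus_cols <- function(loci) {
  as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
}

#' Extract the genotype matrix of a clone data table
#'
#' @param data A clone data tibble.
#' @return Integer matrix with one row per ramet (rownames `sample_id`) and
#'   two columns per locus; within each locus the two alleles are sorted so
#'   that genotypes compare order-insensitively.
#' @export
genotype_matrix <- function(data) {
  loci <- locus_names(data)
  g <- as.matrix(data[locus_cols(loci)])
  storage.mode(g) <- "integer"
  rownames(g) <- data$sample_id
  # sort the two alleles within each locus so (a,b) == (b,a)
  for (j in seq_along(loci)) {
    a <- g[, 2L * j - 1L]
    b <- g[, 2L * j]
    swap <- !is.na(a) & !is.na(b) & a > b
    if (any(swap)) {
      tmp <- a[swap]
      a[swap] <- b[swap]
      b[swap] <- tmp
      g[, 2L * j - 1L] <- a
      g[, 2L * j] <- b
    }
  }
  g
}

#' Which ramets carry a complete multilocus genotype?
#'
#' Units missing one or more allele calls are, by default, excluded from
#' clone discrimination and flagged downstream.
#'
#' @param data A clone data tibble.
#' @return Logical vector, one element per row of `data`.
#' @export
complete_genotypes <- function(data) {
  g <- genotype_matrix(data)
  rowSums(is.na(g)) == 0L
}

#' Validate a clone data table
#'
#' Checks the structural invariants: unique sample ids, finite coordinates,
#' non-empty patch ids, positive allele labels, and no half-called loci
#' (one allele present, the other missing).
#'
#' @param data A clone data tibble.
#' @return `data`, invisibly, if valid; otherwise an error.
#' @export
validate_clone_data <- function(data) {
  stopifnot(is.data.frame(data))
  miss <- setdiff(reserved_cols, names(data))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  dup <- data$sample_id[duplicated(data$sample_id)]
  if (length(dup) > 0) {
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  }
  if (!all(is.finite(data$x)) || !all(is.finite(data$y))) {
    bad <- data$sample_id[!is.finite(data$x) | !is.finite(data$y)]
    stop("non-finite coordinates for: ", paste(bad, collapse = ", "))
  }
  if (any(is.na(data$patch_id) | !nzchar(data$patch_id))) {
    stop("empty patch_id values present")
  }
  loci <- locus_names(data)
  stray <- setdiff(names(data), c(reserved_cols, locus_cols(loci)))
  if (length(stray) > 0) {
    stop("columns not recognised as locus allele pairs: ", paste(stray, collapse = ", "))
  }
  g <- as.matrix(data[locus_cols(loci)])
  if (any(g <= 0, na.rm = TRUE)) stop("allele labels must be positive integers")
  for (j in seq_along(loci)) {
    a <- g[, 2L * j - 1L]
    b <- g[, 2L * j]
    half <- xor(is.na(a), is.na(b))
    if (any(half)) {
      stop(
        "half-called genotypes at locus ", loci[j], " for: ",
        paste(data$sample_id[half], collapse = ", ")
      )
    }
  }
  invisible(data)
}

#' Read a clone data table from disk
#'
#' Two formats are supported.  `"csv"` expects columns `sample_id, x, y,
#' patch_id` followed by `<locus>_1, <locus>_2` pairs; missing calls may be
#' written as `0` or left empty.  `"genalex"` expects a GenAlEx-style
#' codominant export: a first row `n_loci, n_samples, n_pops, <pop sizes>`,
#' a second title row, then a header row `Sample, Pop, <locus>, , ...` with
#' trailing `X, Y` coordinate columns, and one row per sample with `0` for
#' missing calls.
#'
#' Rows with unparseable coordinates or malformed genotypes are rejected
#' with a row-level warning naming the sample; structural problems
#' (duplicate ids, locus count mismatches) are hard errors.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"genalex"`.
#' @return A clone data tibble.
#' @export
read_clone_data <- function(path, format = c("csv", "genalex")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  data <- switch(format,
    csv = read_clone_csv(path),
    genalex = read_genalex(path)
  )
  validate_clone_data(data)
  data
}

read_clone_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  miss <- setdiff(reserved_cols, names(raw))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  loci <- locus_names(raw)
  parse_clone_rows(raw, loci)
}

# Shared row-level parsing: coordinates must be numeric, allele calls integer
# (0/empty = missing); bad rows are dropped with a warning naming them.
parse_clone_rows <- function(raw, loci) {
  n <- nrow(raw)
  x <- suppressWarnings(as.numeric(raw$x))
  y <- suppressWarnings(as.numeric(raw$y))
  cols <- locus_cols(loci)
  g <- suppressWarnings(vapply(raw[cols], as.numeric, numeric(n)))
  g <- matrix(g, nrow = n, dimnames = list(NULL, cols))
  g[!is.na(g) & g == 0] <- NA_real_
  bad_allele <- apply(g, 1L, function(r) {
    any((!is.na(r) & (r != round(r) | r < 0)) | (is.na(r) & !is.na(r)))
  })
  raw_na <- vapply(raw[cols], function(col) is.na(col) | col %in% c("", "0"), logical(n))
  raw_na <- matrix(raw_na, nrow = n)
  unparseable <- is.na(g) & !raw_na  # text that failed numeric conversion
  bad <- !is.finite(x) | !is.finite(y) | bad_allele | rowSums(unparseable) > 0
  if (any(bad)) {
    warning(
      "rejected ", sum(bad), " row(s) with unparseable coordinates or malformed genotypes: ",
      paste(raw$sample_id[bad], collapse = ", ")
    )
  }
  keep <- which(!bad)
  out <- tibble::tibble(
    sample_id = as.character(raw$sample_id[keep]),
    x = x[keep], y = y[keep],
    patch_id = as.character(raw$patch_id[keep])
  )
  gi <- matrix(as.integer(g[keep, , drop = FALSE]), nrow = length(keep),
               dimnames = list(NULL, cols))
  dplyr::bind_cols(out, tibble::as_tibble(gi))
}

#' Write a clone data table
#'
#' @param data A clone data tibble.
#' @param path Output path.
#' @param missing_as How to encode missing allele calls in CSV output
#'   (`0`, the GenAlEx convention, or `NA` for an empty field).
#' @return `path`, invisibly.
#' @export
write_clone_data <- function(data, path, missing_as = 0L) {
  validate_clone_data(data)
  out <- data
  cols <- locus_cols(locus_names(data))
  if (!is.na(missing_as)) {
    out <- dplyr::mutate(out, dplyr::across(
      dplyr::all_of(cols), ~ dplyr::coalesce(.x, as.integer(missing_as))
    ))
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_clone_data
#' @param data A clone data tibble (for the writer).
#' @param title Title placed on the second header row.
#' @export
write_genalex <- function(data, path, title = "clonescape export") {
  validate_clone_data(data)
  loci <- locus_names(data)
  n <- nrow(data)
  line1 <- paste(c(length(loci), n, 1L, n), collapse = ",")
  line2 <- title
  header <- c("Sample", "Pop", as.vector(rbind(loci, "")), "X", "Y")
  g <- as.matrix(data[locus_cols(loci)])
  g[is.na(g)] <- 0L
  body <- cbind(data$sample_id, data$patch_id, g,
                sprintf("%.17g", data$x), sprintf("%.17g", data$y))
  lines <- c(line1, line2, paste(header, collapse = ","),
             apply(body, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

read_genalex <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L) stop("not a GenAlEx codominant file: ", path)
  counts <- suppressWarnings(as.integer(strsplit(lines[1L], ",")[[1]]))
  n_loci <- counts[1L]
  n_samples <- counts[2L]
  if (is.na(n_loci) || is.na(n_samples)) stop("malformed GenAlEx count row")
  header <- strsplit(lines[3L], ",")[[1]]
  loci <- header[seq(3L, by = 2L, length.out = n_loci)]
  if (any(!nzchar(loci))) stop("malformed GenAlEx locus header")
  rows <- strsplit(lines[-(1:3)], ",")
  nf <- 2L + 2L * n_loci + 2L
  bad_len <- which(lengths(rows) != nf)
  if (length(bad_len) > 0) {
    stop("locus count mismatch on data row(s): ", paste(bad_len, collapse = ", "))
  }
  m <- do.call(rbind, rows)
  raw <- tibble::as_tibble(m, .name_repair = "minimal")
  names(raw) <- c("sample_id", "patch_id",
                  locus_cols(loci), "x", "y")
  parse_clone_rows(raw, loci)
}
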