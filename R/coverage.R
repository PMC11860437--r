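#' Validate an MHC allele-frequency table
#'
#' Checks the structural invariants of a frequency extract: columns `locus`,
#' `allele`, `frequency`; frequencies non-negative; allele names unique
#' within a locus; per-locus frequency sums not exceeding 1 (up to `tol`).
#' A per-locus sum below 1 is interpreted as untyped (uncovered) mass.
#'
#' @param table Data frame with columns `locus`, `allele`, `frequency`
#'   (a `population` column is optional).
#' @param tol Tolerance on the per-locus sum (default 1e-9).
#' @return The table, invisibly, as a tibble.
#' @export
validate_allele_table <- function(table, tol = 1e-9) {
  stopifnot(all(c("locus", "allele", "frequency") %in% names(table)))
  if (any(table$frequency < 0)) abort("frequencies must be non-negative")
  totals <- tapply(table$frequency, table$locus, sum)
  bad <- names(totals)[totals > 1 + tol]
  if (length(bad) > 0L) {
    abort(sprintf("locus frequency sum exceeds 1 at: %s",
                  paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(paste(table$locus, table$allele, sep = "\r")) > 0L) {
    dup <- table$locus[duplicated(paste(table$locus, table$allele,
                                        sep = "\r"))]
    abort(sprintf("duplicated allele name within locus: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  invisible(as_tibble(table))
}

covered_allele_freq <- function(table, binding, locus) {
  at_locus <- table[table$locus == locus, , drop = FALSE]
  if (nrow(at_locus) == 0L) abort(sprintf("locus '%s' not in table", locus))
  bound <- binding[binding$locus == locus, , drop = FALSE]
  absent <- setdiff(bound$allele, at_locus$allele)
  if (length(absent) > 0L) {
    abort(sprintf("covered allele(s) absent from table at %s: %s",
                  locus, paste(absent, collapse = ", ")))
  }
  sum(at_locus$frequency[at_locus$allele %in% bound$allele])
}

#' Phenotypic population coverage at one locus
#'
#' Sums the frequencies of the covered alleles at the locus into an allelic
#' coverage `p`, then applies the diploid Hardy-Weinberg phenotypic formula
#' `1 - (1 - p)^2`: the chance that a random individual carries at least one
#' covered allele at the locus.
#'
#' @param table Allele-frequency table (see [validate_allele_table()]).
#' @param binding Data frame of covered alleles with columns `locus`,
#'   `allele`.
#' @param locus Locus name, present in `table`.
#' @param renormalize Divide `p` by the locus frequency sum (use when the
#'   extract is incomplete and you want coverage among typed alleles)?
#'   Default `FALSE`: missing mass counts as uncovered.
#' @return Coverage in `[0, 1]`.
#' @export
#' @examples
#' tab <- tibble::tibble(locus = "DRB1", allele = c("a", "b"),
#'                       frequency = c(0.3, 0.6))
#' locus_coverage(tab, tibble::tibble(locus = "DRB1", allele = "a"), "DRB1")
locus_coverage <- function(table, binding, locus, renormalize = FALSE) {
  validate_allele_table(table)
  locus_coverage_impl(table, binding, locus, renormalize)
}

locus_coverage_impl <- function(table, binding, locus, renormalize) {
  p <- covered_allele_freq(table, binding, locus)
  if (renormalize) {
    total <- sum(table$frequency[table$locus == locus])
    if (total > 0) p <- p / total
  }
  p <- min(p, 1)
  1 - (1 - p)^2
}

#' Combined phenotypic coverage across loci
#'
#' Multiplies the per-locus non-coverage probabilities `(1 - p_locus)^2`
#' over all loci in the table (independence across loci assumed) and
#' returns the complement. With a single locus this equals
#' [locus_coverage()].
#'
#' @inheritParams locus_coverage
#' @return Coverage in `[0, 1]`.
#' @export
combined_coverage <- function(table, binding, renormalize = FALSE) {
  validate_allele_table(table)
  loci <- unique(table$locus)
  if (length(loci) == 0L) abort("table has no loci")
  miss <- purrr::map_dbl(loci, function(l) {
    1 - locus_coverage_impl(table, binding, l, renormalize)
  })
  1 - prod(miss)
}

#' Read allele-frequency and binding-set TSV files
#'
#' Frequency TSV columns: `population`, `locus`, `allele`, `frequency`
#' (population optional). Binding-set TSV columns: `locus`, `allele`.
#'
#' @param path TSV file path.
#' @return A validated tibble.
#' @export
read_allele_table <- function(path) {
  validate_allele_table(readr::read_tsv(path, show_col_types = FALSE,
                                        progress = FALSE))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_allele_table
#' @export
read_binding_set <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("locus", "allele") %in% names(df)))
  df
}
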