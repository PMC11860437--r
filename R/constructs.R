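#' Default motif library for modular vaccine constructs
#'
#' Ordered lookup table mapping literal sequence motifs to the region kind
#' they play in a modular immunogenic construct. The defaults cover the
#' classic building blocks: the CALNN gold-anchoring pentapeptide, the
#' dibasic KK cathepsin-B spacer, the flexible GPGPG spacer, the influenza A
#' haemagglutinin HA306-318 CD4+ T-cell epitope, and the arginine-rich TAT
#' cell-penetrating peptide. Order is priority: when two motifs could claim
#' the same position the earlier row wins.
#'
#' @return A tibble with columns `motif` and `kind`
#'   (`anchor`/`spacer`/`epitope`/`cpp`/`other`).
#' @export
#' @examples
#' default_motif_library()
default_motif_library <- function() {
  tibble(
    motif = c("CALNN", "KK", "GPGPG", "PKYVKQNTLKLAT", "RKKRQRRR"),
    kind  = c("anchor", "spacer", "spacer", "epitope", "cpp")
  )
}

## validate + uppercase a peptide sequence; error names the first offending
## position (B, J, O, U, X, Z and anything non-alphabetic are rejected)
validate_sequence <- function(sequence, id = "peptide") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      !nzchar(sequence)) {
    abort(sprintf("sequence for '%s' must be a non-empty string", id))
  }
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0L) {
    abort(sprintf(
      "invalid amino-acid character '%s' at position %d in sequence '%s'",
      chars[bad[1]], bad[1], id
    ))
  }
  sequence
}

check_motif_library <- function(motif_library) {
  stopifnot(is.data.frame(motif_library),
            all(c("motif", "kind") %in% names(motif_library)))
  kinds <- c("anchor", "spacer", "epitope", "cpp", "other")
  if (!all(motif_library$kind %in% kinds)) {
    abort(sprintf("region kind must be one of: %s",
                  paste(kinds, collapse = ", ")))
  }
  motif_library
}

#' Parse a peptide sequence into an annotated modular construct
#'
#' Scans the sequence left to right and greedily claims non-overlapping
#' motifs from `motif_library`; when several motifs match at the same
#' position the library order decides. Stretches matching no motif are left
#' unannotated.
#'
#' @param id Short construct label.
#' @param sequence One-letter amino-acid string (case-insensitive; the 20
#'   standard residues only).
#' @param motif_library Ordered tibble with columns `motif`, `kind`; see
#'   [default_motif_library()].
#' @param c_terminal_amide Is the C-terminus amidated (the default, as for
#'   constructs assembled on Rink amide resin)? Controls whether the free
#'   C-terminal carboxylate counts as a negative charge in
#'   [charge_summary()].
#' @return A `peptide_construct`: a list with `id`, `sequence`, a `regions`
#'   tibble (`kind`, `start`, `end`, `motif`; 1-based inclusive), and
#'   `c_terminal_amide`.
#' @export
#' @examples
#' p1 <- parse_construct("p1", "CALNNKKPKYVKQNTLKLAT")
#' p1$regions
parse_construct <- function(id, sequence,
                            motif_library = default_motif_library(),
                            c_terminal_amide = TRUE) {
  sequence <- validate_sequence(sequence, id)
  motif_library <- check_motif_library(motif_library)
  L <- nchar(sequence)
  regions <- list()
  pos <- 1L
  while (pos <= L) {
    hit <- NULL
    for (i in seq_len(nrow(motif_library))) {
      m <- motif_library$motif[i]
      w <- nchar(m)
      if (pos + w - 1L <= L && substr(sequence, pos, pos + w - 1L) == m) {
        hit <- i
        break
      }
    }
    if (is.null(hit)) {
      pos <- pos + 1L
    } else {
      w <- nchar(motif_library$motif[hit])
      regions[[length(regions) + 1L]] <- tibble(
        kind  = motif_library$kind[hit],
        start = pos,
        end   = pos + w - 1L,
        motif = motif_library$motif[hit]
      )
      pos <- pos + w
    }
  }
  regions <- if (length(regions) > 0L) {
    dplyr::bind_rows(regions)
  } else {
    tibble(kind = character(), start = integer(), end = integer(),
           motif = character())
  }
  structure(
    list(id = id, sequence = sequence, regions = regions,
         c_terminal_amide = c_terminal_amide),
    class = "peptide_construct"
  )
}

#' @export
print.peptide_construct <- function(x, ...) {
  cat(sprintf("<peptide_construct> %s (%d aa%s)\n", x$id, nchar(x$sequence),
              if (x$c_terminal_amide) ", C-terminal amide" else ""))
  cat(" ", x$sequence, "\n")
  if (nrow(x$regions) > 0L) print(x$regions, n = Inf)
  invisible(x)
}

#' Annotate a table of constructs
#'
#' Data-frame-first wrapper around [parse_construct()]: takes a tibble with
#' `id` and `sequence` columns and returns one row per annotated region.
#'
#' @param constructs Data frame with columns `id`, `sequence`.
#' @inheritParams parse_construct
#' @return A tibble with columns `id`, `kind`, `start`, `end`, `motif`.
#' @export
annotate_constructs <- function(constructs,
                                motif_library = default_motif_library()) {
  stopifnot(all(c("id", "sequence") %in% names(constructs)))
  purrr::map2_dfr(constructs$id, constructs$sequence, function(id, seq) {
    pc <- parse_construct(id, seq, motif_library)
    if (nrow(pc$regions) == 0L) return(tibble())
    dplyr::mutate(pc$regions, id = id, .before = 1)
  })
}

#' Charge and composition summary of a construct
#'
#' Counts ionizable residues and reports net positive/negative charge counts
#' at neutral pH. By convention the positive count is lysine + arginine side
#' chains plus one free N-terminal amine; histidine is excluded by default
#' (mostly uncharged at pH 7). The negative count is aspartate + glutamate
#' plus the free C-terminal carboxylate unless the construct is amidated.
#'
#' @param x A `peptide_construct`, a bare sequence string, or a data frame
#'   with `id` and `sequence` columns (one summary row per row).
#' @param include_histidine Count histidine as positively charged?
#' @param count_n_terminus Count the free N-terminal amine as one positive
#'   charge?
#' @param ... Passed between methods.
#' @return A tibble with columns `id`, `n_lys`, `n_arg`, `n_his`, `n_asp`,
#'   `n_glu`, `n_nterm`, `n_positive`, `n_negative`.
#' @export
#' @examples
#' charge_summary(parse_construct("p2", "CALNNKKPKYVKQNTLKLATRKKRQRRR"))
charge_summary <- function(x, ...) {
  UseMethod("charge_summary")
}

#' @rdname charge_summary
#' @export
charge_summary.peptide_construct <- function(x, include_histidine = FALSE,
                                             count_n_terminus = TRUE, ...) {
  chars <- strsplit(x$sequence, "")[[1]]
  n <- function(a) sum(chars == a)
  n_nterm <- as.integer(count_n_terminus)
  n_positive <- n("K") + n("R") + n_nterm +
    if (include_histidine) n("H") else 0L
  n_negative <- n("D") + n("E") + as.integer(!x$c_terminal_amide)
  tibble(
    id = x$id, n_lys = n("K"), n_arg = n("R"), n_his = n("H"),
    n_asp = n("D"), n_glu = n("E"), n_nterm = n_nterm,
    n_positive = n_positive, n_negative = n_negative
  )
}

#' @rdname charge_summary
#' @export
charge_summary.character <- function(x, include_histidine = FALSE,
                                     count_n_terminus = TRUE, ...) {
  charge_summary(parse_construct("peptide", x),
                 include_histidine = include_histidine,
                 count_n_terminus = count_n_terminus)
}

#' @rdname charge_summary
#' @export
charge_summary.data.frame <- function(x, include_histidine = FALSE,
                                      count_n_terminus = TRUE, ...) {
  stopifnot(all(c("id", "sequence") %in% names(x)))
  purrr::map2_dfr(x$id, x$sequence, function(id, seq) {
    charge_summary(parse_construct(id, seq),
                   include_histidine = include_histidine,
                   count_n_terminus = count_n_terminus)
  })
}

#' Locate every occurrence of an epitope core
#'
#' Exact substring scan, including overlapping matches.
#'
#' @param construct A `peptide_construct` or a bare sequence string.
#' @param core Non-empty query sequence (e.g. a nonameric MHC binding core).
#' @return Integer vector of 1-based start positions (possibly empty).
#' @export
#' @examples
#' p1 <- parse_construct("p1", "CALNNKKPKYVKQNTLKLAT")
#' locate_epitope_core(p1, "YVKQNTLKL")
locate_epitope_core <- function(construct, core) {
  sequence <- if (inherits(construct, "peptide_construct")) {
    construct$sequence
  } else {
    validate_sequence(construct)
  }
  if (!is.character(core) || length(core) != 1L || !nzchar(core)) {
    abort("core must be a non-empty string")
  }
  core <- toupper(core)
  hits <- gregexpr(paste0("(?=", core, ")"), sequence, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer() else as.integer(hits)
}

#' Read and write construct FASTA
#'
#' The record id is the construct id; the description carries the region
#' annotation as `kind:start-end` tokens so a round trip preserves id and
#' sequence exactly.
#'
#' @param path FASTA file path.
#' @param motif_library Motif library used to (re-)annotate on read.
#' @param c_terminal_amide Amidation flag applied to all records on read.
#' @return `read_construct_fasta()`: a list of `peptide_construct`s.
#' @export
read_construct_fasta <- function(path,
                                 motif_library = default_motif_library(),
                                 c_terminal_amide = TRUE) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  purrr::map2(ids, as.character(set), parse_construct,
              motif_library = motif_library,
              c_terminal_amide = c_terminal_amide)
}

#' @rdname read_construct_fasta
#' @param constructs A `peptide_construct` or list of them.
#' @return `write_construct_fasta()`: the path, invisibly.
#' @export
write_construct_fasta <- function(constructs, path) {
  if (inherits(constructs, "peptide_construct")) constructs <- list(constructs)
  headers <- purrr::map_chr(constructs, function(pc) {
    ann <- if (nrow(pc$regions) > 0L) {
      paste(sprintf("%s:%d-%d", pc$regions$kind, pc$regions$start,
                    pc$regions$end), collapse = " ")
    } else ""
    trimws(paste(pc$id, ann))
  })
  set <- Biostrings::AAStringSet(purrr::map_chr(constructs, "sequence"))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
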