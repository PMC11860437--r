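#' Configuration for the synthetic-data generators
#'
#' One config object drives every generator so a whole pipeline's worth of
#' inputs can be regenerated from a single seed. Defaults emulate the study
#' conditions: constructs built as CALNN anchor + spacer (KK or GPGPG) +
#' epitope-like core + optional TAT-derived tail; a dose grid spanning
#' 10 pM - 100,000 pM around an IC50 of 3308 pM with upper asymptote 100%
#' viability; five replicates; class-II-style loci with Dirichlet allele
#' frequencies leaving 5% untyped mass.
#'
#' @param seed Integer seed; the same config always regenerates identical
#'   data.
#' @param core_length Range (min, max) of the random epitope-like core.
#' @param spacer_prob Probability a construct gets a spacer.
#' @param cpp_prob Probability a construct gets the cell-penetrating tail.
#' @param anchor,spacers,cpp Literal motifs used to assemble constructs.
#' @param matrix_mean,matrix_sd Background score distribution of synthetic
#'   specificity matrices.
#' @param dibasic_bonus Score bonus added for K/R at the P1 and P2 subsites
#'   (cathepsin-B-like dibasic preference); 0 = no planted preference.
#' @param dose_grid Dose grid in pM (>= 4 distinct doses).
#' @param truth_4pl Named list `lower`, `upper`, `ic50`, `hill`: the
#'   generating truth of dose-response plates.
#' @param noise_sd Additive Gaussian noise SD on responses (response units).
#' @param n_replicates Replicates per dose.
#' @param loci Locus names for allele tables.
#' @param alleles_per_locus Alleles drawn per locus.
#' @param dirichlet_concentration Symmetric Dirichlet concentration for
#'   allele frequencies (large = near-uniform).
#' @param typed_mass Total frequency mass assigned per locus (<= 1; the
#'   remainder models untyped alleles).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             core_length = c(9L, 15L),
                             spacer_prob = 1,
                             cpp_prob = 0.5,
                             anchor = "CALNN",
                             spacers = c("KK", "GPGPG"),
                             cpp = "RKKRQRRR",
                             matrix_mean = 0,
                             matrix_sd = 1,
                             dibasic_bonus = 0,
                             dose_grid = 10^seq(1, 5, by = 0.5),
                             truth_4pl = list(lower = 0, upper = 100,
                                              ic50 = 3308, hill = 1),
                             noise_sd = 0,
                             n_replicates = 5L,
                             loci = c("DRB1", "DQB1", "DPB1"),
                             alleles_per_locus = 10L,
                             dirichlet_concentration = 1,
                             typed_mass = 0.95) {
  stopifnot(length(core_length) == 2L, core_length[1] >= 1L,
            core_length[2] >= core_length[1],
            spacer_prob >= 0, spacer_prob <= 1,
            cpp_prob >= 0, cpp_prob <= 1,
            matrix_sd >= 0, length(dose_grid) >= 4L,
            all(c("lower", "upper", "ic50", "hill") %in% names(truth_4pl)),
            noise_sd >= 0, n_replicates >= 1L, length(loci) >= 1L,
            alleles_per_locus >= 1L, dirichlet_concentration > 0,
            typed_mass > 0, typed_mass <= 1)
  structure(
    list(seed = as.integer(seed), core_length = as.integer(core_length),
         spacer_prob = spacer_prob, cpp_prob = cpp_prob, anchor = anchor,
         spacers = spacers, cpp = cpp, matrix_mean = matrix_mean,
         matrix_sd = matrix_sd, dibasic_bonus = dibasic_bonus,
         dose_grid = dose_grid, truth_4pl = truth_4pl, noise_sd = noise_sd,
         n_replicates = as.integer(n_replicates), loci = loci,
         alleles_per_locus = as.integer(alleles_per_locus),
         dirichlet_concentration = dirichlet_concentration,
         typed_mass = typed_mass),
    class = "generator_config"
  )
}

## each generator draws from its own deterministic stream so that adding a
## generator never perturbs the others; offsets are arbitrary but fixed
gen_seed <- function(cfg, offset) (cfg$seed + offset) %% .Machine$integer.max

#' Generate synthetic modular peptide constructs
#'
#' Assembles `n` constructs as anchor + optional spacer + random epitope-like
#' core + optional cell-penetrating tail, emitting the planted region truth
#' alongside each sequence so annotation can be tested against it.
#'
#' @param cfg A [generator_config()].
#' @param n Number of constructs (>= 1).
#' @return Tibble with `id`, `sequence` and a `regions` list-column of truth
#'   tibbles (`kind`, `start`, `end`, `motif`).
#' @export
#' @examples
#' make_peptides(generator_config(seed = 7), 3)
make_peptides <- function(cfg, n) {
  stopifnot(inherits(cfg, "generator_config"))
  if (n < 1L) abort("n must be >= 1")
  withr::with_seed(gen_seed(cfg, 101L), {
    purrr::map_dfr(seq_len(n), function(i) {
      parts <- list(c(kind = "anchor", motif = cfg$anchor))
      if (stats::runif(1) < cfg$spacer_prob) {
        parts <- c(parts, list(c(kind = "spacer",
                                 motif = sample(cfg$spacers, 1L))))
      }
      core_len <- sample(seq(cfg$core_length[1], cfg$core_length[2]), 1L)
      core <- paste(sample(AA_ALPHABET, core_len, replace = TRUE),
                    collapse = "")
      parts <- c(parts, list(c(kind = "epitope", motif = core)))
      if (stats::runif(1) < cfg$cpp_prob) {
        parts <- c(parts, list(c(kind = "cpp", motif = cfg$cpp)))
      }
      motifs <- purrr::map_chr(parts, "motif")
      ends <- cumsum(nchar(motifs))
      starts <- ends - nchar(motifs) + 1L
      tibble(
        id = sprintf("syn%03d", i),
        sequence = paste(motifs, collapse = ""),
        regions = list(tibble(kind = purrr::map_chr(parts, "kind"),
                              start = as.integer(starts),
                              end = as.integer(ends), motif = motifs))
      )
    })
  })
}

#' Generate a synthetic specificity matrix
#'
#' Background scores are i.i.d. Normal(`matrix_mean`, `matrix_sd`); on top,
#' `dibasic_bonus` is added for K and R at the P1 and P2 subsites, planting
#' the cathepsin-B-like dibasic preference. As the bonus grows relative to
#' the background SD, the dibasic bond of a KK-containing peptide becomes
#' the top-ranked cut with probability approaching 1.
#'
#' @param cfg A [generator_config()].
#' @return A `specificity_matrix` (8 x 20).
#' @export
make_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::with_seed(gen_seed(cfg, 202L), {
    scores <- matrix(rnorm(160L, cfg$matrix_mean, cfg$matrix_sd),
                     nrow = 8L, dimnames = list(SUBSITES, AA_ALPHABET))
    scores[c("P1", "P2"), c("K", "R")] <-
      scores[c("P1", "P2"), c("K", "R")] + cfg$dibasic_bonus
    specificity_matrix(
      scores, protease = "synthetic",
      provenance = sprintf(
        "synthetic: N(%g, %g) background, dibasic bonus %g at P1/P2, seed %d",
        cfg$matrix_mean, cfg$matrix_sd, cfg$dibasic_bonus, cfg$seed)
    )
  })
}

#' Generate a synthetic dose-response plate
#'
#' Responses are the four-parameter logistic truth evaluated on the dose
#' grid plus additive Gaussian noise, `n_replicates` per dose. The truth is
#' attached as the `truth` attribute so recovery tests never reverse-
#' engineer it.
#'
#' @param cfg A [generator_config()].
#' @return Tibble with `dose`, `replicate`, `response`; attribute `truth`.
#' @export
#' @examples
#' plate <- make_dose_response(generator_config(seed = 3, noise_sd = 2))
#' attr(plate, "truth")$ic50
make_dose_response <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  t4 <- cfg$truth_4pl
  withr::with_seed(gen_seed(cfg, 303L), {
    grid <- tidyr::expand_grid(dose = cfg$dose_grid,
                               replicate = seq_len(cfg$n_replicates))
    grid$response <- four_pl(grid$dose, t4$lower, t4$upper, t4$ic50,
                             t4$hill) +
      rnorm(nrow(grid), 0, cfg$noise_sd)
    attr(grid, "truth") <- t4
    grid
  })
}

#' Generate a synthetic allele-frequency table
#'
#' Per locus, `alleles_per_locus` frequencies are drawn from a symmetric
#' Dirichlet (via normalized Gamma draws) and scaled to `typed_mass`, so
#' per-locus sums never exceed 1 and the table is valid by construction.
#'
#' @param cfg A [generator_config()].
#' @return Tibble with `population`, `locus`, `allele`, `frequency`.
#' @export
make_allele_table <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::with_seed(gen_seed(cfg, 404L), {
    tab <- purrr::map_dfr(cfg$loci, function(l) {
      g <- rgamma(cfg$alleles_per_locus, shape = cfg$dirichlet_concentration)
      tibble(
        population = "synthetic",
        locus = l,
        allele = sprintf("%s*%02d", l, seq_len(cfg$alleles_per_locus)),
        frequency = g / sum(g) * cfg$typed_mass
      )
    })
    validate_allele_table(tab)
    tab
  })
}
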