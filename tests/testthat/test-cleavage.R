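test_that("matrix TSV reader validates shape and values", {
  zeros <- specificity_matrix(matrix(0, 8, 20), "null", "test")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_specificity_matrix(zeros, path)
  back <- read_specificity_matrix(path)
  expect_equal(back$scores, zeros$scores)
  expect_equal(back$protease, "null")

  # all-zero matrix: every window scores 0
  s <- score_windows("CALNNKKPKYVKQNTLKLAT", zeros)
  expect_true(all(s$score == 0))
  expect_equal(s$bond, 4:16)  # ties broken by ascending bond

  # a 7-row table errors naming the missing subsite
  lines <- readLines(path)
  writeLines(lines[-length(lines)], path)  # drop the P4' row
  expect_error(read_specificity_matrix(path), "P4'")

  # non-numeric cell
  lines2 <- readLines(system.file("extdata", "cathepsin_b_matrix_synthetic.tsv",
                                  package = "nanopep"))
  lines2[3] <- sub("\t0\t", "\tx\t", lines2[3])
  writeLines(lines2, path)
  expect_error(read_specificity_matrix(path), "numeric")
})

test_that("bundled cathepsin-B fixture loads with protease metadata", {
  m <- cathepsin_b_matrix()
  expect_equal(m$protease, "cathepsin B")
  expect_equal(dim(m$scores), c(8L, 20L))
  expect_match(m$provenance, "synthetic")
  # hallmark dibasic preference at the P1/P2 subsites
  expect_gt(m$scores["P1", "K"], 0)
  expect_gt(m$scores["P1", "R"], 0)
  expect_gt(m$scores["P2", "K"], 0)
})

test_that("window scores are the plain sum of aligned subsite scores", {
  # K scores 1 at every subsite, everything else 0
  m <- matrix(0, 8, 20, dimnames = list(NULL, AA20))
  m[, "K"] <- 1
  mk <- specificity_matrix(m, "K-counter", "test")
  s <- score_windows("KKKKAAAAKK", mk)
  score_at <- function(b) s$score[s$bond == b]
  expect_equal(score_at(4), 4)  # window KKKKAAAA
  expect_equal(score_at(5), 4)  # window KKKAAAAK
  expect_equal(score_at(6), 4)  # window KKAAAAKK
  expect_equal(s$bond[s$rank == 1], 4L)  # tie-break by position
  expect_error(score_windows("KKKKAAA", mk), "too short")
})

test_that("window scoring matches the brute-force oracle on random inputs", {
  set.seed(101)
  for (i in 1:200) {
    seqc <- random_sequence(sample(8:40, 1))
    mat <- random_specificity_matrix()
    got <- score_windows(seqc, mat)
    want <- brute_force_scores(seqc, mat)
    got <- got[order(got$bond), ]
    expect_equal(got$bond, want$bond)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("prepending neutral residues shifts bonds without changing scores", {
  set.seed(7)
  mat <- random_specificity_matrix()
  mat$scores[, "G"] <- 0  # make glycine score-neutral at every subsite
  seqc <- random_sequence(20)
  base <- score_windows(seqc, mat)
  shifted <- score_windows(paste0("GGGG", seqc), mat)
  # every interior bond of the original appears 4 positions later with the
  # same score
  for (i in seq_len(nrow(base))) {
    b <- base$bond[i]
    expect_equal(shifted$score[shifted$bond == b + 4L], base$score[i],
                 tolerance = 1e-12)
  }
})

test_that("raising a residue's P1 score never demotes bonds cutting after it", {
  set.seed(33)
  for (i in 1:20) {
    seqc <- random_sequence(sample(12:30, 1))
    mat <- random_specificity_matrix()
    chars <- strsplit(seqc, "")[[1]]
    r <- sample(unique(chars[4:(nchar(seqc) - 4)]), 1)
    before <- score_windows(seqc, mat)
    mat2 <- mat
    mat2$scores["P1", r] <- mat2$scores["P1", r] + 2
    after <- score_windows(seqc, mat2)
    affected <- before$bond[chars[before$bond] == r]
    for (b in affected) {
      expect_lte(after$rank[after$bond == b], before$rank[before$bond == b])
    }
  }
})

test_that("top-site selection honours k and the tie-break rule", {
  sites <- tibble::tibble(bond = c(4L, 6L, 8L, 10L, 12L),
                          window = "x", score = c(5, 5, 3, 2, 1))
  sites <- dplyr::arrange(sites, dplyr::desc(score), bond)
  sites$rank <- 1:5
  expect_equal(select_top_sites(sites, 3)$bond, c(4L, 6L, 8L))
  expect_equal(nrow(select_top_sites(sites[1:2, ], 3)), 2L)  # k exceeds n
  expect_equal(select_top_sites(sites, 1)$bond, 4L)  # equal scores: lower bond
})

test_that("single-cut fragments conserve the parent and deduplicate", {
  p1 <- parse_construct("p1", "CALNNKKPKYVKQNTLKLAT")
  sites <- score_windows(p1, cathepsin_b_matrix())
  sel <- select_top_sites(sites, 3)
  rep <- enumerate_fragments(p1, sel, sites = sites)
  # each cut's two fragments reconstruct the parent
  for (b in unique(rep$fragments$bond)) {
    pair <- rep$fragments[rep$fragments$bond == b, ]
    if (nrow(pair) == 2L) {
      expect_identical(paste0(pair$fragment[pair$side == "N"],
                              pair$fragment[pair$side == "C"]),
                       p1$sequence)
    }
  }
  # fragments equal the slice they claim
  expect_identical(rep$fragments$fragment,
                   substring(p1$sequence, rep$fragments$start,
                             rep$fragments$end))
  # no duplicated sequences
  expect_false(anyDuplicated(rep$fragments$fragment) > 0)
  # zero selected sites -> empty fragment list
  empty <- enumerate_fragments(p1, sel[0, ])
  expect_equal(nrow(empty$fragments), 0L)
})

test_that("fragment sets for the four constructs match the published table", {
  m <- cathepsin_b_matrix()
  pubs <- published_fragments()
  for (i in seq_len(nrow(study_constructs()))) {
    row <- study_constructs()[i, ]
    rep <- predict_cleavage(parse_construct(row$id, row$sequence), m,
                            k = 3, core = "YVKQNTLKL")
    expect_setequal(rep$fragments$fragment, pubs[[row$id]])
    expect_true(rep$epitope_released)
  }
})

test_that("expected cut positions sit on the spacer/epitope boundaries", {
  m <- cathepsin_b_matrix()
  bonds <- function(seqc) {
    sort(select_top_sites(score_windows(seqc, m), 3)$bond)
  }
  tab <- study_constructs()
  expect_equal(bonds(tab$sequence[1]), c(5L, 9L, 15L))
  expect_equal(bonds(tab$sequence[2]), c(9L, 15L, 17L))
  expect_equal(bonds(tab$sequence[3]), c(5L, 8L, 18L))
  expect_equal(bonds(tab$sequence[4]), c(5L, 18L, 20L))
})

test_that("epitope release check scans fragments for the core", {
  expect_true(epitope_release_check(published_fragments()$p1, "YVKQNTLKL"))
  expect_false(epitope_release_check(c("CALNN", "LKLAT"), "YVKQNTLKL"))
  expect_false(epitope_release_check(character(), "YVKQNTLKL"))
  expect_error(epitope_release_check(character(), ""), "non-empty")
})

test_that("motif preference reports the best rank touching each region", {
  p1 <- parse_construct("p1", "CALNNKKPKYVKQNTLKLAT")
  sites <- score_windows(p1, cathepsin_b_matrix())
  pref <- motif_preference_report(p1, sites)
  # brute-force recomputation of the overlap rule
  for (j in seq_len(nrow(pref))) {
    hit <- sites$rank[sites$bond >= pref$start[j] - 1L &
                      sites$bond <= pref$end[j]]
    expect_equal(pref$best_rank[j],
                 if (length(hit) == 0) NA_integer_ else min(hit))
  }
  # the top-ranked cut flanks the epitope; the spacer hosts a selected cut
  expect_equal(pref$best_rank[pref$kind == "epitope"], 1L)
  expect_lte(pref$best_rank[pref$kind == "spacer"], 3L)
  # no regions -> empty mapping
  bare <- parse_construct("x", random_sequence(12),
                          motif_library = default_motif_library()[0, ])
  expect_equal(nrow(motif_preference_report(bare, sites)), 0L)
  # single region covering the whole sequence gets the best overall rank
  lib <- tibble::tibble(motif = p1$sequence, kind = "other")
  whole <- parse_construct("w", p1$sequence, motif_library = lib)
  expect_equal(motif_preference_report(whole, sites)$best_rank, 1L)
})
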