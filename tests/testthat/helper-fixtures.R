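# The four study constructs (anchor + spacer + HA306-318 epitope +/- TAT tail)
study_constructs <- function() {
  tibble::tibble(
    id = c("p1", "p2", "p3", "p4"),
    sequence = c(
      "CALNNKKPKYVKQNTLKLAT",
      "CALNNKKPKYVKQNTLKLATRKKRQRRR",
      "CALNNGPGPGPKYVKQNTLKLAT",
      "CALNNGPGPGPKYVKQNTLKLATRKKRQRRR"
    )
  )
}

# published single-cut fragment sets (six per construct, three cuts each)
published_fragments <- function() {
  list(
    p1 = c("CALNNKKPKYVKQNT", "KKPKYVKQNTLKLAT", "YVKQNTLKLAT",
           "CALNNKKPK", "CALNN", "LKLAT"),
    p2 = c("YVKQNTLKLATRKKRQRRR", "CALNNKKPKYVKQNTLK", "CALNNKKPKYVKQNT",
           "LKLATRKKRQRRR", "LATRKKRQRRR", "CALNNKKPK"),
    p3 = c("CALNNGPGPGPKYVKQNT", "GPGPGPKYVKQNTLKLAT", "PGPKYVKQNTLKLAT",
           "CALNNGPG", "CALNN", "LKLAT"),
    p4 = c("GPGPGPKYVKQNTLKLATRKKRQRRR", "CALNNGPGPGPKYVKQNTLK",
           "CALNNGPGPGPKYVKQNT", "LKLATRKKRQRRR", "LATRKKRQRRR", "CALNN")
  )
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_sequence <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

random_specificity_matrix <- function(sd = 1) {
  m <- matrix(stats::rnorm(160, 0, sd), nrow = 8,
              dimnames = list(c("P4", "P3", "P2", "P1",
                                "P1'", "P2'", "P3'", "P4'"), AA20))
  specificity_matrix(m, protease = "random", provenance = "test")
}

# independent window scorer: explicit double loop, no shared code with
# score_windows()
brute_force_scores <- function(sequence, mat) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  bonds <- 4:(L - 4)
  scores <- numeric(length(bonds))
  for (i in seq_along(bonds)) {
    p <- bonds[i]
    s <- 0
    for (j in 1:8) {
      s <- s + mat$scores[j, chars[p - 4 + j]]
    }
    scores[i] <- s
  }
  data.frame(bond = bonds, score = scores)
}
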