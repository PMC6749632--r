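## Small hand-built pedigrees used across test files.

## A, B founders; C their offspring
trioPed <- function() {
  Pedigree(data.frame(id = c("A", "B", "C"), sire = c("0", "0", "A"),
                      dam = c("0", "0", "B"),
                      sex = c("male", "female", "female")))
}

## full sibs C, D of unrelated founders A, B; E their (incestuous) offspring
fullSibPed <- function() {
  Pedigree(data.frame(id = c("A", "B", "C", "D", "E"),
                      sire = c("0", "0", "A", "A", "C"),
                      dam = c("0", "0", "B", "B", "D"),
                      sex = c("male", "female", "male", "female", "female")))
}

## half sibs sharing sire A; F their offspring
halfSibPed <- function() {
  Pedigree(data.frame(id = c("A", "B", "B2", "C", "D", "F"),
                      sire = c("0", "0", "0", "A", "A", "C"),
                      dam = c("0", "0", "0", "B", "B2", "D"),
                      sex = c("male", "female", "female", "male",
                              "female", "male")))
}

## proband E whose sire S and dam D are both children of ancestor A through
## disjoint unrelated mates U1, U2
disjointPathPed <- function() {
  Pedigree(data.frame(id = c("A", "U1", "U2", "S", "D", "E"),
                      sire = c("0", "0", "0", "A", "A", "S"),
                      dam = c("0", "0", "0", "U1", "U2", "D"),
                      sex = c("male", "female", "female", "male",
                              "female", "female")))
}

## proband E whose sire S and dam D are half sibs through the SAME child X
## of ancestor A: sire and dam transmissions are dependent, so the product
## formula underestimates the joint homozygosity probability
sharedPathPed <- function() {
  Pedigree(data.frame(id = c("A", "B", "X", "U1", "U2", "S", "D", "E"),
                      sire = c("0", "0", "A", "0", "0", "X", "X", "S"),
                      dam = c("0", "0", "B", "0", "0", "U1", "U2", "D"),
                      sex = c("male", "female", "male", "female", "female",
                              "male", "female", "female")))
}

## one sire with n progeny carrying given death ages (NA = unknown status)
sireProgenyPed <- function(deathAges, cause = NULL, sireId = "SIRE") {
  n <- length(deathAges)
  d <- data.frame(id = c(sireId, "DAM", sprintf("%s_C%04d", sireId, seq_len(n))),
                  sire = c("0", "0", rep(sireId, n)),
                  dam = c("0", "0", rep("DAM", n)),
                  sex = c("male", "female", rep("unknown", n)),
                  birth_year = c(NA, NA, rep(2010L, n)),
                  death_age_months = c(NA, NA, deathAges),
                  stringsAsFactors = FALSE)
  if (!is.null(cause)) d$cause <- c(NA, NA, cause)
  Pedigree(d)
}

## population of nSires sires, each with nProgeny calves whose window-death
## indicator is Bernoulli(p)
multiSirePed <- function(nSires, nProgeny, p, seed) {
  set.seed(seed)
  rows <- list(data.frame(id = sprintf("S%03d", seq_len(nSires)),
                          sire = "0", dam = "0", sex = "male",
                          death_age_months = NA_real_,
                          stringsAsFactors = FALSE),
               data.frame(id = "DAM0", sire = "0", dam = "0",
                          sex = "female", death_age_months = NA_real_,
                          stringsAsFactors = FALSE))
  for (s in seq_len(nSires)) {
    died <- runif(nProgeny) < p
    rows[[length(rows) + 1L]] <-
      data.frame(id = sprintf("S%03d_C%04d", s, seq_len(nProgeny)),
                 sire = sprintf("S%03d", s), dam = "DAM0", sex = "unknown",
                 death_age_months = ifelse(died, round(runif(nProgeny, 0, 6), 1),
                                           round(runif(nProgeny, 7, 120), 1)),
                 stringsAsFactors = FALSE)
  }
  Pedigree(do.call(rbind, rows))
}

quadratFixture <- function() {
  readQuadrats(system.file("extdata", "hed_quadrats.csv",
                           package = "pedcase"))
}
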