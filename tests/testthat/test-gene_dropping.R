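test_that("exact contribution recursion gives the Mendelian expectations", {
  ped <- disjointPathPed()
  ec <- expectedContribution(ped, "A")
  expect_equal(contributionOf(ec, "A"), 1)
  expect_equal(contributionOf(ec, "S"), 0.5)   # one meiosis
  expect_equal(contributionOf(ec, "E"), 0.5)   # both parents children of A
  expect_equal(contributionOf(ec, "U1"), 0)    # unrelated founder
  grand <- Pedigree(data.frame(id = c("A", "B", "C", "D", "E"),
                               sire = c(0, 0, "A", "C", 0),
                               dam = c(0, 0, "B", "E", 0)))
  expect_equal(contributionOf(expectedContribution(grand, "A"), "D"), 0.25)
  expect_error(expectedContribution(ped, "NOPE"), "unknown")
})

test_that("contributions of all founders sum to one when ancestry is complete", {
  sim <- simulatePedigree(nFounders = 20, nGenerations = 3,
                          loopAncestors = 5, seed = 101)
  ped <- sim$pedigree
  d <- pedigreeTable(ped)
  founders <- d$id[is.na(d$sire) & is.na(d$dam)]
  tot <- Reduce(`+`, lapply(founders, function(f)
    contributions(expectedContribution(ped, f))$c))
  expect_equal(tot, rep(1, nIndividuals(ped)), tolerance = 1e-12)
})

test_that("gene dropping matches its known expectations and zero-path exactness", {
  ped <- disjointPathPed()
  gd <- geneDropContribution(ped, "A", nReps = 10000, seed = 5)
  est <- contributions(gd)
  ## S always inherits exactly one labelled allele from A (both of A's
  ## alleles are labelled), so the estimate is exactly 0.5 with zero se
  i <- match("S", est$id)
  expect_lte(abs(est$c[i] - 0.5), 3 * est$se[i])
  ## a genuinely stochastic case: grandchild through one line
  grand <- Pedigree(data.frame(id = c("A", "B", "C", "D", "E"),
                               sire = c(0, 0, "A", "C", 0),
                               dam = c(0, 0, "B", "E", 0)))
  gg <- contributions(geneDropContribution(grand, "A", nReps = 10000,
                                           seed = 6))
  k <- match("D", gg$id)
  expect_gt(gg$se[k], 0)
  expect_lt(abs(gg$c[k] - 0.25), 3 * gg$se[k])
  ## no descent path: exactly zero with zero se
  j <- match("U1", est$id)
  expect_identical(est$c[j], 0)
  expect_identical(est$se[j], 0)
  ## fixed seed => bit-identical
  gd2 <- geneDropContribution(ped, "A", nReps = 10000, seed = 5)
  expect_identical(contributions(gd), contributions(gd2))
  expect_error(geneDropContribution(ped, "A", nReps = 0, seed = 1), "nReps")
})

test_that("gene dropping converges to the exact recursion across a pedigree", {
  sim <- simulatePedigree(nFounders = 30, nGenerations = 3,
                          loopAncestors = 8, seed = 111)
  ped <- sim$pedigree
  anc <- sim$truth$carrier
  exact <- contributions(expectedContribution(ped, anc))$c
  hits <- 0L; tot <- 0L
  for (seed in 1:20) {
    est <- contributions(geneDropContribution(ped, anc, nReps = 10000,
                                              seed = seed))
    ok <- abs(est$c - exact) <= 3 * est$se + 1e-12
    hits <- hits + sum(ok)
    tot <- tot + length(ok)
  }
  expect_gte(hits / tot, 0.99)
})

test_that("Monte-Carlo error shrinks as 1/sqrt(n_reps)", {
  sim <- simulatePedigree(nFounders = 20, nGenerations = 3,
                          loopAncestors = 5, seed = 121)
  ped <- sim$pedigree
  anc <- sim$truth$carrier
  exact <- contributions(expectedContribution(ped, anc))$c
  err <- function(nReps, seed)
    mean(abs(contributions(geneDropContribution(ped, anc, nReps = nReps,
                                                seed = seed))$c - exact))
  e100 <- mean(vapply(1:8, function(s) err(100, s), numeric(1)))
  e10k <- mean(vapply(1:8, function(s) err(10000, s + 100), numeric(1)))
  ## expected ratio sqrt(10000/100) = 10
  expect_gt(e100 / e10k, 5)
  expect_lt(e100 / e10k, 20)
})

test_that("the homozygosity product formula behaves as stated", {
  expect_equal(homozygosityProbability(0.5, 0.5), 0.0625)
  expect_equal(homozygosityProbability(1, 1), 0.25)
  expect_equal(homozygosityProbability(0, runif(5)), rep(0, 5))
  expect_error(homozygosityProbability(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(homozygosityProbability(0.5, 1.2), "\\[0, 1\\]")
  ## symmetric and monotone non-decreasing in each argument
  set.seed(1)
  for (k in 1:20) {
    a <- runif(1); b <- runif(1); eps <- runif(1, 0, 1 - a)
    expect_identical(homozygosityProbability(a, b),
                     homozygosityProbability(b, a))
    expect_gte(homozygosityProbability(a + eps, b),
               homozygosityProbability(a, b))
  }
})

test_that("joint gene-drop homozygosity matches exhaustive enumeration", {
  ## disjoint parental paths: enumeration equals the product formula 0.0625
  ped <- disjointPathPed()
  exact <- oracleJointHomozygosity(ped, "A", "E")
  expect_equal(exact, homozygosityProbability(0.5, 0.5))
  jh <- jointHomozygosityGeneDrop(ped, "A", "E", nReps = 40000, seed = 9)
  expect_lt(abs(jh$p_hat - exact), 3 * jh$se)
  ## unrelated dam: probability identically zero
  d <- pedigreeTable(ped)
  d$dam[d$id == "E"] <- "U2"  # U2 is an unrelated founder
  ped0 <- Pedigree(d)
  expect_equal(oracleJointHomozygosity(ped0, "A", "E"), 0)
  expect_equal(jointHomozygosityGeneDrop(ped0, "A", "E", nReps = 2000,
                                         seed = 2)$p_hat, 0)
})

test_that("shared-loop dependence makes the product formula undercount, and the gene drop sees it", {
  ped <- sharedPathPed()
  exact <- oracleJointHomozygosity(ped, "A", "E")
  expect_equal(exact, 1 / 32)  # enumeration: both transmissions through X
  prod <- homozygosityProbability(
    contributionOf(expectedContribution(ped, "A"), "S"),
    contributionOf(expectedContribution(ped, "A"), "D"))
  expect_equal(prod, 1 / 64)   # the independence assumption halves it
  jh <- jointHomozygosityGeneDrop(ped, "A", "E", nReps = 60000, seed = 13)
  expect_lt(abs(jh$p_hat - exact), 3 * jh$se)
  expect_gt(abs(jh$p_hat - prod), 3 * jh$se)
})

test_that("expected cases sum p_homo over calves in the birth-year window", {
  d <- pedigreeTable(disjointPathPed())
  d$birth_year <- c(2000L, 2000L, 2000L, 2004L, 2004L, 2008L)
  ped <- Pedigree(d)
  ce <- expectedCases(ped, "A", c(2008, 2008))
  expect_equal(expectedTotal(ce), 0.0625)
  expect_equal(unname(expectedPerYear(ce)["2008"]), 0.0625)
  expect_equal(expectedTotal(expectedCases(ped, "A", c(1990, 1995))), 0)
  ## additive over disjoint year ranges
  sim <- simulatePedigree(nFounders = 12, nGenerations = 4,
                          offspringPerMating = list(dist = "poisson",
                                                    lambda = 2.5),
                          loopAncestors = 4, seed = 131)
  yr <- range(pedigreeTable(sim$pedigree)$birth_year)
  anc <- sim$truth$carrier
  whole <- expectedTotal(expectedCases(sim$pedigree, anc, yr))
  mid <- floor(mean(yr))
  split <- expectedTotal(expectedCases(sim$pedigree, anc, c(yr[1], mid))) +
    expectedTotal(expectedCases(sim$pedigree, anc, c(mid + 1, yr[2])))
  expect_equal(whole, split, tolerance = 1e-12)
})

test_that("expected cases agree with forward Mendelian simulation", {
  sim <- simulatePedigree(nFounders = 8, nGenerations = 6,
                          offspringPerMating = list(dist = "poisson",
                                                    lambda = 3),
                          loopAncestors = 0, proband = FALSE, seed = 141)
  ped <- sim$pedigree
  anc <- pedIds(ped)[1L]
  yr <- range(pedigreeTable(ped)$birth_year)
  ce <- expectedCases(ped, anc, yr)
  lambda <- expectedTotal(ce)
  expect_gt(lambda, 0.2)  # the check must have signal
  inRange <- ce@perIndividual$id
  counts <- vapply(1:50, function(s) {
    drop <- plantCarrierAndDrop(ped, anc, seed = 1000 + s)
    sum(drop$affected[inRange])
  }, numeric(1))
  ## the empirical se is the correct uncertainty of the forward mean: a
  ## pure binomial se would ignore the covariance of sibs sharing parental
  ## transmissions
  seEmp <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - lambda), 3 * seEmp)
})
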