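## Progeny mortality screens and the rule-based inheritance-mode verdict.

.isParentOf <- function(ped, id) {
  d <- ped@data
  (!is.na(d$sire) & d$sire == id) | (!is.na(d$dam) & d$dam == id)
}

#' Early-life mortality rate in the progeny of one sire
#'
#' Fraction of progeny whose recorded age at death falls inside the closed
#' age window (default 0-6 months), among progeny with known survival
#' status. Status is known iff \code{death_age_months} is recorded. When the
#' pedigree carries a \code{cause} column, only deaths with \code{cause ==
#' "natural"} are counted in the numerator (culled or unknown-cause animals
#' stay in the denominator). The count of unknown-status progeny is attached
#' as attribute \code{nUnknown}.
#'
#' @param ped a [Pedigree-class].
#' @param sire parent identifier (matched in both parent roles).
#' @param ageWindowMonths closed window \code{c(low, high)} in months.
#' @return mortality rate in [0, 1], with attributes \code{nKnown},
#'   \code{nUnknown}, \code{nDied}.
#' @export
progenyMortality <- function(ped, sire, ageWindowMonths = c(0, 6)) {
  .idIndex(ped, sire, "sire")
  d <- ped@data
  prog <- which(.isParentOf(ped, sire))
  if (!length(prog)) stop("'", sire, "' has no recorded progeny")
  known <- !is.na(d$death_age_months[prog])
  if (!any(known))
    stop("no progeny of '", sire, "' has a known survival status")
  inWin <- known & d$death_age_months[prog] >= ageWindowMonths[1L] &
    d$death_age_months[prog] <= ageWindowMonths[2L]
  natural <- if (all(is.na(d$cause))) rep(TRUE, length(prog)) else
    is.na(d$cause[prog]) | d$cause[prog] == "natural"
  died <- inWin & natural
  rate <- sum(died) / sum(known)
  structure(rate, nKnown = sum(known), nUnknown = sum(!known),
            nDied = sum(died))
}

#' Population distribution of sire progeny mortality
#'
#' Mean and sample standard deviation of the per-sire early-life mortality
#' rate over all sires with strictly more than \code{minDescendants}
#' progeny.
#'
#' @param ped a [Pedigree-class].
#' @param minDescendants qualifying sires have more than this many progeny
#'   (default 100, strict).
#' @param ageWindowMonths closed age window in months.
#' @return list with \code{mean}, \code{sd}, \code{nSires} and the named
#'   per-sire \code{rates}.
#' @export
populationMortality <- function(ped, minDescendants = 100,
                                ageWindowMonths = c(0, 6)) {
  d <- ped@data
  cnt <- table(c(d$sire[!is.na(d$sire)], d$dam[!is.na(d$dam)]))
  sires <- names(cnt)[cnt > minDescendants & names(cnt) %in% d$id[d$sex != "female"]]
  ## restrict to male parents when sex is recorded; otherwise any parent
  if (!length(sires))
    sires <- names(cnt)[cnt > minDescendants]
  if (length(sires) < 2L)
    stop("fewer than 2 sires with more than ", minDescendants, " progeny")
  rates <- vapply(sires, function(s)
    as.numeric(progenyMortality(ped, s, ageWindowMonths)), numeric(1))
  list(mean = mean(rates), sd = stats::sd(rates), nSires = length(sires),
       rates = rates)
}

#' Standardized mortality statistics for one sire
#'
#' Convenience wrapper combining [progenyMortality()] for a focal sire with
#' [populationMortality()] of all qualifying sires, reporting the
#' standardized deviation z = (rate - mean) / sd.
#'
#' @inheritParams populationMortality
#' @param sire focal sire identifier.
#' @return data.frame row with \code{sire}, \code{n_descendants},
#'   \code{rate}, \code{population_mean}, \code{population_sd}, \code{z}.
#' @export
mortalityStats <- function(ped, sire, minDescendants = 100,
                           ageWindowMonths = c(0, 6)) {
  r <- progenyMortality(ped, sire, ageWindowMonths)
  popm <- populationMortality(ped, minDescendants, ageWindowMonths)
  data.frame(sire = sire,
             n_descendants = sum(.isParentOf(ped, sire)),
             rate = as.numeric(r),
             population_mean = popm$mean,
             population_sd = popm$sd,
             z = if (popm$sd > 0) (as.numeric(r) - popm$mean) / popm$sd
                 else NA_real_,
             stringsAsFactors = FALSE)
}

#' Assess the mode of inheritance of an isolated case
#'
#' Formalizes the rejection of recessive inheritance as a Poisson
#' zero-observation argument: if the least-exposed common-lineage ancestor,
#' were it a carrier, would still have produced more than
#' \code{rejectionThreshold} expected affected calves while zero other cases
#' were observed, recessive inheritance is implausible (the probability of
#' observing zero cases given expectation lambda, exp(-lambda), is
#' reported). When recessive inheritance is rejected and both parents are
#' recorded unaffected, a de novo dominant mutation is assumed.
#'
#' @param ped a [Pedigree-class].
#' @param proband proband identifier.
#' @param expectedCaseResults list of [CaseExpectation-class] objects, one
#'   per common-lineage ancestor (e.g. from [expectedCases()]).
#' @param observedOtherCases number of other reported cases (default 0).
#' @param rejectionThreshold expected-case threshold above which a zero
#'   observation rejects the recessive hypothesis (default 5).
#' @param mortality optional list from [populationMortality()] or a
#'   [mortalityStats()] row, carried into the report.
#' @return an [InheritanceReport-class].
#' @export
assessInheritance <- function(ped, proband, expectedCaseResults,
                              observedOtherCases = 0,
                              rejectionThreshold = 5, mortality = NULL) {
  if (!length(expectedCaseResults))
    stop("expectedCaseResults must be non-empty")
  i <- .idIndex(ped, proband, "proband")
  d <- ped@data
  totals <- vapply(expectedCaseResults, expectedTotal, numeric(1))
  ancs <- vapply(expectedCaseResults, function(x) x@ancestor, character(1))
  lambdaMin <- min(totals)
  recessivePlausible <- !(lambdaMin > rejectionThreshold &&
                            observedOtherCases == 0)
  parentsUnaffected <- {
    si <- match(d$sire[i], d$id); di <- match(d$dam[i], d$id)
    !is.na(si) && !is.na(di) &&
      d$phenotype[si] == "unaffected" && d$phenotype[di] == "unaffected"
  }
  verdict <- if (recessivePlausible) "recessive_plausible"
    else if (parentsUnaffected) "de_novo_dominant_assumed"
    else "inconclusive"
  cohortF <- if (!is.na(d$birth_year[i]))
    cohortMeanInbreeding(ped, d$birth_year[i]) else NA_real_
  loops <- if (!is.na(d$sire[i]) && !is.na(d$dam[i]))
    commonLineageAncestors(ped, proband) else character(0)
  if (is.list(mortality) && is.null(mortality$rates) &&
      !is.data.frame(mortality)) mortality <- as.list(mortality)
  new("InheritanceReport",
      proband = proband,
      probandF = inbreedingCoefficient(ped, proband),
      cohortF = cohortF,
      loopAncestors = loops,
      expectedCases = data.frame(ancestor = ancs, expected_total = totals,
                                 stringsAsFactors = FALSE),
      observedOtherCases = as.numeric(observedOtherCases),
      recessivePlausible = recessivePlausible,
      poissonZeroProb = exp(-lambdaMin),
      verdict = verdict,
      mortality = if (is.null(mortality)) NULL else as.list(mortality))
}

setMethod("show", "InheritanceReport", function(object) {
  cat("Inheritance assessment for proband", object@proband, "\n")
  cat(sprintf("  inbreeding: proband F = %.4f, birth-cohort mean F = %.4f\n",
              object@probandF, object@cohortF))
  cat("  common-lineage ancestors (pedigree loops):",
      length(object@loopAncestors), "\n")
  cat(sprintf("  expected recessive cases: min %.3g, max %.3g over %d ancestors\n",
              min(object@expectedCases$expected_total),
              max(object@expectedCases$expected_total),
              nrow(object@expectedCases)))
  cat(sprintf("  P(0 observed cases | min expectation) = %.3g\n",
              object@poissonZeroProb))
  cat("  recessive plausible:", object@recessivePlausible, "\n")
  cat("  verdict:", object@verdict, "\n")
})
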