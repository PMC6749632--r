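## Ancestral genetic contributions, the homozygosity product formula, and
## expected recessive-case counts. The contribution c(i) of an ancestor to an
## individual i is the expected fraction of i's two alleles that descend from
## the ancestor's two alleles: exactly computable by a linear recursion in
## topological order, and estimable by Monte-Carlo gene dropping.

#' @useDynLib pedcase, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.cppArgs <- function(ped) {
  p <- .parentIdx(ped)
  list(order = ped@topo - 1L,
       sire = ifelse(is.na(p$si), -1L, p$si - 1L),
       dam = ifelse(is.na(p$di), -1L, p$di - 1L))
}

#' Exact ancestral contribution by recursion
#'
#' Exact expectation of the gene-dropped contribution: c(ancestor) = 1 and,
#' in topological order, c(i) = (c(sire_i) + c(dam_i)) / 2 with an unknown
#' parent contributing 0. If the ancestor's own parents are recorded,
#' transmission into the ancestor is overridden by c(ancestor) = 1: the
#' ancestor's two alleles are the tracked source.
#'
#' @param ped a [Pedigree-class].
#' @param ancestor ancestor identifier.
#' @return a [ContributionEstimate-class] with \code{method = "recursion"}
#'   and se identically 0.
#' @seealso [geneDropContribution()] for the Monte-Carlo estimator.
#' @export
expectedContribution <- function(ped, ancestor) {
  a <- .idIndex(ped, ancestor, "ancestor")
  p <- .parentIdx(ped)
  n <- nIndividuals(ped)
  cc <- numeric(n)
  for (i in ped@topo) {
    if (i == a) { cc[i] <- 1; next }
    s <- p$si[i]; d <- p$di[i]
    cc[i] <- 0.5 * ((if (is.na(s)) 0 else cc[s]) + (if (is.na(d)) 0 else cc[d]))
  }
  new("ContributionEstimate", ancestor = ancestor,
      estimates = data.frame(id = ped@data$id, c = cc, se = 0,
                             stringsAsFactors = FALSE),
      method = "recursion", nReps = NA_real_, seed = NA_real_)
}

#' Ancestral contribution by Monte-Carlo gene dropping
#'
#' Per replicate, the ancestor's two alleles are labelled and every other
#' founder carries unlabelled alleles; each non-founder inherits one
#' uniformly random allele from each recorded parent (an unknown parent
#' contributes an unlabelled allele). c(i) is the mean over replicates of
#' the labelled-allele fraction in i; the standard error is the sample
#' standard deviation of that per-replicate fraction divided by
#' sqrt(n_reps). Individuals with no descent path from the ancestor get
#' exactly 0 with se 0. Results are bit-identical for a fixed seed.
#'
#' @param ped a [Pedigree-class].
#' @param ancestor ancestor identifier.
#' @param nReps number of replicates (default 10,000).
#' @param seed integer RNG seed (required, for reproducibility).
#' @return a [ContributionEstimate-class] with \code{method = "gene_drop"}.
#' @export
geneDropContribution <- function(ped, ancestor, nReps = 10000, seed) {
  if (missing(seed)) stop("a seed is required for gene dropping")
  if (!is.numeric(nReps) || nReps < 1) stop("nReps must be >= 1")
  a <- .idIndex(ped, ancestor, "ancestor")
  arg <- .cppArgs(ped)
  set.seed(seed)
  res <- .gene_drop_cpp(arg$order, arg$sire, arg$dam, a - 1L, as.integer(nReps))
  new("ContributionEstimate", ancestor = ancestor,
      estimates = data.frame(id = ped@data$id, c = res$c, se = res$se,
                             stringsAsFactors = FALSE),
      method = "gene_drop", nReps = as.numeric(nReps), seed = as.numeric(seed))
}

#' @describeIn ContributionEstimate contribution estimates as a data.frame
#' @param x a [ContributionEstimate-class].
#' @export
contributions <- function(x) x@estimates

#' @describeIn ContributionEstimate contribution of one individual
#' @param id individual identifier.
#' @export
contributionOf <- function(x, id) {
  i <- match(id, x@estimates$id)
  if (is.na(i)) stop("unknown individual id: '", id, "'")
  x@estimates$c[i]
}

setMethod("show", "ContributionEstimate", function(object) {
  cat("ContributionEstimate for ancestor", object@ancestor,
      "(", object@method, ")\n")
  if (object@method == "gene_drop")
    cat("  replicates:", object@nReps, " seed:", object@seed, "\n")
  cat("  individuals with c > 0:", sum(object@estimates$c > 0), "of",
      nrow(object@estimates), "\n")
})

#' Homozygosity probability from parental contributions
#'
#' Probability that a calf is homozygous for an allele of the tracked
#' carrier ancestor, under independent parental transmissions:
#' p_homo = c(sire) * c(dam) / 4. The factor 1/4 is the chance that each
#' parent passes specifically the mutant one of the carrier-derived pair.
#'
#' @param cSire,cDam parental contributions in [0, 1]; vectorized.
#' @return p_homo in [0, 0.25].
#' @examples
#' homozygosityProbability(0.5, 0.5)   # 0.0625
#' @export
homozygosityProbability <- function(cSire, cDam) {
  if (any(cSire < 0 | cSire > 1, na.rm = TRUE) ||
      any(cDam < 0 | cDam > 1, na.rm = TRUE))
    stop("contributions must lie in [0, 1]")
  cSire * cDam / 4
}

#' Joint homozygosity probability by gene dropping
#'
#' Monte-Carlo diagnostic for the product formula: per replicate one of the
#' ancestor's two alleles is marked mutant, alleles drop through the
#' pedigree by Mendelian sampling, and the estimate is the fraction of
#' replicates in which the proband carries two mutant copies. Unlike the
#' product formula this respects any dependence between the sire's and the
#' dam's transmissions through shared loops.
#'
#' @param ped a [Pedigree-class].
#' @param ancestor carrier ancestor identifier.
#' @param proband proband identifier; both parents must be recorded.
#' @param nReps number of replicates (default 10,000).
#' @param seed integer RNG seed (required).
#' @return list with \code{p_hat}, binomial \code{se}, and \code{n_reps}.
#' @export
jointHomozygosityGeneDrop <- function(ped, ancestor, proband,
                                      nReps = 10000, seed) {
  if (missing(seed)) stop("a seed is required for gene dropping")
  if (!is.numeric(nReps) || nReps < 1) stop("nReps must be >= 1")
  a <- .idIndex(ped, ancestor, "ancestor")
  i <- .idIndex(ped, proband, "proband")
  p <- .parentIdx(ped)
  if (is.na(p$si[i]) || is.na(p$di[i]))
    stop("proband '", proband, "' must have both parents recorded")
  arg <- .cppArgs(ped)
  set.seed(seed)
  .joint_homo_cpp(arg$order, arg$sire, arg$dam, a - 1L, i - 1L,
                  as.integer(nReps))
}

#' Expected recessive-homozygote cases for one ancestor
#'
#' For every calf born in the year range with both parents recorded,
#' computes p_homo = c(sire) * c(dam) / 4 from the exact recursion-based
#' contributions of the ancestor, and sums per birth year and in total:
#' the expected number of affected calves if the ancestor carried a fully
#' penetrant recessive mutation. Calves with an unknown parent are
#' excluded (p_homo is undefined without both contributions).
#'
#' @param ped a [Pedigree-class].
#' @param ancestor ancestor identifier.
#' @param yearRange inclusive \code{c(start, end)} birth-year range.
#' @return a [CaseExpectation-class].
#' @export
expectedCases <- function(ped, ancestor, yearRange) {
  stopifnot(length(yearRange) == 2L, yearRange[2L] >= yearRange[1L])
  contrib <- expectedContribution(ped, ancestor)
  cc <- contrib@estimates$c
  d <- ped@data
  p <- .parentIdx(ped)
  keep <- !is.na(d$birth_year) &
    d$birth_year >= yearRange[1L] & d$birth_year <= yearRange[2L] &
    !is.na(p$si) & !is.na(p$di)
  idx <- which(keep)
  pHomo <- homozygosityProbability(cc[p$si[idx]], cc[p$di[idx]])
  years <- seq.int(yearRange[1L], yearRange[2L])
  perYear <- setNames(numeric(length(years)), years)
  if (length(idx)) {
    agg <- tapply(pHomo, d$birth_year[idx], sum)
    perYear[names(agg)] <- agg
  }
  new("CaseExpectation", ancestor = ancestor,
      yearRange = as.numeric(yearRange),
      perIndividual = data.frame(id = d$id[idx],
                                 birth_year = d$birth_year[idx],
                                 p_homo = pHomo, stringsAsFactors = FALSE),
      expectedPerYear = perYear,
      expectedTotal = sum(pHomo))
}

#' @describeIn CaseExpectation expected total case count
#' @param x a [CaseExpectation-class].
#' @export
expectedTotal <- function(x) x@expectedTotal

#' @describeIn CaseExpectation expected case count per birth year
#' @export
expectedPerYear <- function(x) x@expectedPerYear

setMethod("show", "CaseExpectation", function(object) {
  cat("CaseExpectation for ancestor", object@ancestor, "over birth years",
      object@yearRange[1L], "-", object@yearRange[2L], "\n")
  cat("  calves with both parents known:", nrow(object@perIndividual), "\n")
  cat("  expected affected total:", format(object@expectedTotal, digits = 4),
      "\n")
})
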