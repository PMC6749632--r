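#' @import methods
#' @importFrom stats rpois runif sd setNames
#' @importFrom utils read.table write.table head
#' @importClassesFrom GenomicRanges GRanges
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))

#' Pedigree of individuals with parentage, demographic and phenotype records
#'
#' A validated, topologically ordered parentage structure. Each individual has
#' an identifier, optional sire and dam identifiers (\code{NA} = unknown
#' parent), a sex, a birth year, an age at death in months, a phenotype, and
#' optionally a cause of death. The parentage graph must be acyclic and every
#' referenced parent must be present.
#'
#' @slot data \code{data.frame} with columns \code{id}, \code{sire},
#'   \code{dam}, \code{sex}, \code{birth_year}, \code{death_age_months},
#'   \code{phenotype}, \code{cause}; rows are kept in input order.
#' @slot topo integer vector: row indices in a topological order (every parent
#'   precedes all of its offspring; ties broken by input order).
#'
#' @seealso [readPedigree()], [kinshipMatrix()], [simulatePedigree()]
#' @export
setClass("Pedigree", representation(data = "data.frame", topo = "integer"))

#' Pairwise kinship coefficient matrix
#'
#' Symmetric matrix of kinship coefficients phi(i, j): the probability that an
#' allele sampled at random from i and one from j are identical by descent.
#' The diagonal carries (1 + F_i) / 2, so founders have 0.5. Row and column
#' names are the individual identifiers, in pedigree input order.
#'
#' @export
setClass("KinshipMatrix", contains = "matrix")

#' Ancestral genetic contribution estimates
#'
#' Per-individual genetic contribution c(i) of one ancestor: the expected
#' fraction of i's two alleles that descend from the ancestor's two alleles.
#' Computed either exactly by the linear recursion (\code{method =
#' "recursion"}, se identically 0) or by Monte-Carlo gene dropping
#' (\code{method = "gene_drop"}, with a standard error per individual).
#'
#' @slot ancestor ancestor identifier.
#' @slot estimates \code{data.frame} with columns \code{id}, \code{c},
#'   \code{se}.
#' @slot method \code{"recursion"} or \code{"gene_drop"}.
#' @slot nReps number of gene-dropping replicates (\code{NA} for recursion).
#' @slot seed RNG seed used (\code{NA} for recursion).
#' @export
setClass("ContributionEstimate",
  representation(ancestor = "character", estimates = "data.frame",
                 method = "character", nReps = "numeric", seed = "numeric"))

#' Expected recessive-homozygote case counts for one ancestor
#'
#' For one putative carrier ancestor and a range of birth years, the
#' per-calf probability of being homozygous for an allele inherited from
#' that ancestor, p_homo = c(sire) * c(dam) / 4, and its sums per birth
#' year and in total.
#'
#' @slot ancestor ancestor identifier.
#' @slot yearRange inclusive \code{c(start, end)} birth-year range.
#' @slot perIndividual \code{data.frame} with columns \code{id},
#'   \code{birth_year}, \code{p_homo} (calves with both parents known only).
#' @slot expectedPerYear named numeric, one entry per year in the range.
#' @slot expectedTotal sum of \code{p_homo} over all calves in the range.
#' @export
setClass("CaseExpectation",
  representation(ancestor = "character", yearRange = "numeric",
                 perIndividual = "data.frame", expectedPerYear = "numeric",
                 expectedTotal = "numeric"))

#' Structural-variant junction call
#'
#' Result of aligning a junction-spanning sequence back onto its two
#' reference flanks: the duplicated / microhomologous segment at the join,
#' any deleted reference bases, any untemplated inserted bases, and the
#' implied repair-mechanism label.
#'
#' @slot duplicatedSegment nucleotide string (possibly empty) shared between
#'   the two flank matches or copied from the left flank at the join.
#' @slot deletedBases reference bases absent from the junction.
#' @slot insertedBases untemplated bases present only in the junction.
#' @slot mechanism one of \code{"MMBIR_like"}, \code{"NHEJ_like"},
#'   \code{"blunt"}, \code{"unresolved"}.
#' @slot diagnostics character; non-empty when the call is unresolved.
#' @seealso [classifyJunction()]
#' @export
setClass("JunctionCall",
  representation(duplicatedSegment = "character", deletedBases = "character",
                 insertedBases = "character", mechanism = "character",
                 diagnostics = "character"))

#' Windowed read-depth profile
#'
#' Mean read depth in non-overlapping, tiling genomic windows, with a masked
#' flag for windows intersecting excluded regions (e.g. satellite repeats).
#'
#' @slot windows \code{GRanges} with metadata columns \code{meanDepth} and
#'   \code{masked}.
#' @slot windowSize window width in bp.
#' @seealso [depthProfile()], [copyNumberFlag()]
#' @export
setClass("DepthProfile",
  representation(windows = "GRanges", windowSize = "numeric"))

#' Inheritance-mode assessment report
#'
#' Rule-based verdict on the mode of inheritance of an isolated case:
#' recessive inheritance is rejected when, for every ancestor common to the
#' proband's two lineages, the expected number of recessive-homozygous
#' affected calves exceeds a threshold while no other case was observed
#' (with the Poisson probability of observing zero cases reported), and a
#' de novo dominant mutation is assumed when both parents are unaffected.
#'
#' @slot proband proband identifier.
#' @slot probandF proband inbreeding coefficient.
#' @slot cohortF mean inbreeding coefficient of the proband's birth cohort.
#' @slot loopAncestors identifiers common to both parental lineages.
#' @slot expectedCases \code{data.frame} with columns \code{ancestor},
#'   \code{expected_total}.
#' @slot observedOtherCases integer count of other reported cases.
#' @slot recessivePlausible logical.
#' @slot poissonZeroProb exp(-lambda_min): probability of observing zero
#'   cases if the least-exposed common ancestor were a carrier.
#' @slot verdict \code{"recessive_plausible"},
#'   \code{"de_novo_dominant_assumed"} or \code{"inconclusive"}.
#' @slot mortality optional list from [populationMortality()] context.
#' @export
setClass("InheritanceReport",
  representation(proband = "character", probandF = "numeric",
                 cohortF = "numeric", loopAncestors = "character",
                 expectedCases = "data.frame", observedOtherCases = "numeric",
                 recessivePlausible = "logical", poissonZeroProb = "numeric",
                 verdict = "character", mortality = "listOrNULL"))
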