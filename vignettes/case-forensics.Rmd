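---
title: "Forensics of an isolated congenital disease case: pedigree, variants and breakpoints"
author: "pedcase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forensics of an isolated congenital disease case}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedcase)
```

# The problem

An isolated case of a distinctive congenital syndrome — here, hypohidrotic
ectodermal dysplasia (HED) in a female dairy calf born to two unaffected
parents — poses a mode-of-inheritance question before any sequence is
looked at. If the causal allele were a recessive mutation inherited from a
shared ancestor, the same national population should have produced other
affected calves; if it is dominant and de novo, the case should be unique
and the causal variant should be heterozygous in the case and absent from
every control genome. `pedcase` implements the computational chain that
turns this argument into numbers, plus the sequence-level follow-up once a
structural variant is found: breakpoint repair-signature classification,
dotplot motif scans, read-depth copy-number checks, and the skin
morphometry that quantifies the phenotype.

# Pedigree model

## Kinship and inbreeding

Kinship `phi(i, j)` is the probability that one allele sampled from `i` and
one from `j` are identical by descent. It is computed by the standard
tabular recursion in a topological order of the pedigree,

```
phi(i, i) = 0.5 * (1 + phi(sire_i, dam_i))
phi(i, j) = 0.5 * (phi(sire_i, j) + phi(dam_i, j)),  j before i,
```

with unknown-parent terms contributing 0. This recursion fills the rows of
the kinship matrix in the same order in which a Cholesky factorization of
that matrix is built, so it is algebraically the same construction used by
classic livestock pedigree software. The inbreeding coefficient is
`F_i = phi(sire_i, dam_i)`, identically `2 * phi(i, i) - 1`. The dense
matrix is limited to 20,000 individuals (a ~3 GB double matrix); beyond
that, `kinshipPair()` evaluates single pairs by a memoized recursion.

Correctness is tested against an independent oracle: Wright's path
counting, `phi(i, j) = sum over common ancestors A and path pairs sharing
only A of (1/2)^(n1 + n2 + 1) * (1 + F_A)`, enumerated explicitly on
pedigrees of up to 60 individuals and required to agree to 1e-12.

## Common-lineage ancestors (pedigree loops)

`commonLineageAncestors()` intersects the ancestor sets of the proband's
sire and dam (each including the parent itself). Every member of the
intersection closes at least one loop through the proband and is therefore
a candidate source of autozygosity. The proband must have both parents
recorded; anything less is an explicit error rather than a silent empty
answer.

## Genetic contributions and gene dropping

The contribution `c(i)` of an ancestor to individual `i` is defined as the
expected fraction of `i`'s two alleles that descend from the ancestor's two
alleles. Two estimators are provided and cross-checked:

* `expectedContribution()` — the exact linear recursion
  `c(i) = (c(sire_i) + c(dam_i)) / 2` with `c(ancestor) = 1`.
* `geneDropContribution()` — Monte-Carlo gene dropping: the ancestor's two
  alleles are labelled, every meiosis transmits one uniformly random
  parental allele, and `c(i)` is the mean labelled-allele fraction over
  replicates (default 10,000; the core is compiled C++ driven by R's RNG,
  so a fixed seed gives bit-identical results).

The reported standard error is the empirical standard deviation of the
per-replicate fraction divided by `sqrt(n_reps)` rather than a plain
binomial formula: an individual's two alleles are not independent draws
(a child of the ancestor receives a labelled allele with certainty), and
the empirical form is exact in the degenerate cases and correct in
general.

## The recessive-case expectation

For a putative carrier ancestor, the probability that a calf with
contributions `c(sire)` and `c(dam)` is homozygous for the carrier's
mutant allele is taken as

```
p_homo = c(sire) * c(dam) / 4
```

— each parent must pass specifically the mutant one of the two tracked
alleles, hence the factor `(1/2)^2` on the product of contributions.
`expectedCases()` sums `p_homo` over all calves born in a year window with
both parents recorded (a calf with an unknown parent has no defined
`p_homo` and is excluded).

The product assumes the two parental transmissions are independent. That
is false when the sire and dam are connected through a shared non-ancestor
path, and `jointHomozygosityGeneDrop()` is shipped as the honest
diagnostic: it estimates the joint probability directly by gene dropping.
The test suite includes a pedigree in which the exact enumerated
probability is 1/32 while the product formula gives 1/64; the gene-drop
estimator recovers the former and the discrepancy is asserted, not hidden.

## The inheritance verdict

`assessInheritance()` formalizes the qualitative rejection of recessive
inheritance as a Poisson zero-observation argument. With
`lambda_min = min` over common-lineage ancestors of the expected affected
count, and zero other reported cases, the probability of the observation
under the recessive hypothesis is `exp(-lambda_min)`; recessive
inheritance is called implausible when `lambda_min` exceeds a configurable
threshold (default 5, i.e. `P < exp(-5) ~ 0.007`) with zero observed
cases. When it is rejected and both parents are recorded unaffected, the
verdict is a de novo dominant mutation; with an affected parent the
verdict stays inconclusive. The threshold is a formalization choice — the
argument it encodes is qualitative — and the report always carries the
exact `exp(-lambda)` alongside the boolean.

## Progeny mortality screen

Undetected affected calves would surface as excess early-life mortality in
a carrier sire's progeny. `progenyMortality()` computes the fraction of
progeny dying inside a closed age window (default 0-6 months) among
progeny with known status; `populationMortality()` gives the mean and
standard deviation of that rate over all sires with strictly more than a
minimum number of progeny (default 100). When a `cause` column is present
only natural deaths count; progeny with no recorded death age are treated
as status-unknown, excluded from the denominator and reported.

# Variant prioritization

Under the de novo dominant hypothesis the causal small variant must be
heterozygous in the case, absent from a control panel of population
genomes, and of credible quality. `filterPrivateHet()` applies exactly
that: genotype `het`, quality strictly greater than 30, and exact
`(chrom, pos, ref, alt)` key absence from the panel. Coordinates are
1-based (VCF); multi-allelic records are split on reading; alleles with a
shared trailing base are normalized on the fly with a warning so the key
comparison is parsimonious. Panel absence is site-and-allele exact, not
genotype-aware: the panel is a set of observed variants, which is how
population panels are distributed at desk scale. `countProteinAltering()`
then tallies the consequence classes (missense, frameshift, inframe
insertion/deletion, stop gained/lost) supplied by an external annotation
table — annotation engines are consumed as input, never re-implemented.

# Breakpoint characterization

## Junction classification

A junction-spanning sequence is anchored onto its two reference flanks
with exact 20-bp seeds (first occurrence in the left flank, last in the
right) and each anchor is extended base by base. The signature at the join
is read off deterministically:

* anchor overlap — a segment matched by both flanks: shared
  microhomology;
* a gap whose leading bases equal the left-flank suffix — a copy of
  reference sequence inserted at the join: a (partial) duplication, the
  reconstruction of a microhomology-mediated template switch. Matching is
  left-flank-sided, which is the orientation such duplications have here;
* remaining gap bases — untemplated insertion;
* flank bases not reached by either anchor — deletion.

The mechanism label is `MMBIR_like` iff the duplicated/microhomologous
length reaches `minMicrohomology` (default 2), so a 12-bp duplication is
MMBIR-like while a single lost or shared base stays `NHEJ_like`; an exact
end join is `blunt`. Where several (prefix, suffix) decompositions tie,
the seed-and-extend procedure maximizes the duplicated overlap and takes
the leftmost, making calls reproducible. A junction that fails to anchor
in either flank returns `unresolved` with a diagnostic rather than a
guess.

A breakpoint "between positions p and p+1" is stored as `leftPos = p`;
the inversion length is the difference of the two `leftPos` values, with
the Mb figure rounded half-up to one decimal (3,763,389 bp prints as
3.8 Mb).

## Dotplot

`dotplotMatches()` reports every exact word match (default word size 10,
both strands) between two sequences as 1-based start coordinates; `N`
never matches. On uniform random 500-bp flanks the expected forward match
count is `(491)^2 / 4^10 ~ 0.23`, which the tests verify against Poisson
bounds — the absence of repeated motifs around a breakpoint is evidence
that no homology promoted the rearrangement. The word size is a
convention (dotplot tools at this scale default to ~10 with exact
matching); it is exposed as a parameter.

## Depth windows and copy-number neutrality

`depthProfile()` tiles a chromosome into non-overlapping windows anchored
at position 1 (default 10 kb) and averages depth per window, accepting
per-base or per-window input; mask intervals (BED, 0-based half-open,
converted internally) flag windows to exclude — e.g. satellite arrays.
`copyNumberFlag()` compares the mean of unmasked windows inside an
interval against those entirely outside; the interval is copy-neutral when
the ratio lies within `[1/foldThreshold, foldThreshold]`.

One boundary deserves a note: a single-copy duplication in a diploid has
an expected ratio of exactly 1.5, which sits on the edge of the default
1.5 band — a point comparison there is a coin flip on noise. The default
band is kept at 1.5 for the neutrality statement, and the tests detect
het-scale CNVs (0.5x and 1.5x) with a detection threshold of 1.4, a
margin strictly below the expected het ratio.

# Histology quadrats

`quadratSummary()` averages hair count, pilary-canal diameter and
hair-covered area per group over 1-mm^2 quadrats, rounding half-up at the
precision the measurements are reported at (one decimal for counts and
diameters, integers for areas; half-up reproduces all printed values,
which half-even would not). `foldChanges()` reports the hair-count fold as
affected/control and the diameter fold as control/affected — each in the
direction of the observed shift. With three quadrats per group no
hypothesis test is attempted; the summaries are descriptive.

# The synthetic-data generators

Every pipeline stage is exercised against generated data with a
machine-readable ground truth; all generators are deterministic given a
seed.

* `simulatePedigree()` builds a random-mating multi-generation population
  plus, optionally, a proband whose parental lineages share exactly a
  planted set of common ancestors (founders re-used on both sides through
  side-specific descent chains, so the intersection is exactly the planted
  set). Defaults encode the study conditions: 10 planted loop ancestors,
  a 0-6-month death probability of 0.1093, one generation per 3 years.
  Founder sexes are balanced (a breeding nucleus has both sires and dams;
  a Bernoulli draw can collapse small simulated populations).
* `plantCarrierAndDrop()` is the forward Mendelian simulation used to
  validate `expectedCases()` backward computation.
* `simulateVariantTable()` plants private heterozygous candidates with
  quality > 30 among panel-shared, low-quality (one pinned at exactly
  30.00, the strict-inequality boundary), homozygous and hom-ref
  distractors, and writes a deterministic minimal VCF 4.2.
* `simulateJunction()` embeds a configured duplication / deletion /
  insertion at a join of 500-bp uniform-random flanks and verifies its own
  truth by running the classifier internally, regenerating flanks on a
  collision (bounded retries) — the non-repetitive-join guarantee is by
  construction-and-check, not by hope.
* `simulateDepth()` draws window totals as Poisson(mean x fold x window),
  the copy-neutral base mean defaulting to 13.8x; partially overlapping
  windows get an overlap-weighted rate.

What the generators do not emulate: linkage and multi-locus inheritance,
realistic cattle demography and selection, genome sequence composition
(flanks are uniform A/C/G/T, which is what makes the dotplot expectation
closed-form), overdispersed coverage (Poisson, not negative binomial), and
genotype-level panel data. Passing tests therefore demonstrate the
algorithms' correctness on data with the assumed statistical structure,
not robustness to alignment artifacts, segmental duplications or
population structure in real genomes.

# Numerical and interface choices

* Unknown parents: `"0"`, empty and `NA` all mean unknown — the two
  dominant livestock pedigree dialects plus R's native missing value.
* Topological order is stable by input order; ties never reorder.
* A parentage cycle names an individual on the cycle in the error.
* Referenced-but-absent parents are auto-created as founders by default
  (a config flag turns this into an error).
* Monte-Carlo sizes: 10,000 replicates by default; a seed is mandatory
  for every stochastic entry point.
* Problem sizes used in the shipped tests: the oracle comparisons run on
  pedigrees of <= 60 individuals, the gene-drop convergence check on a
  ~4,000-individual pedigree at 10,000 replicates, the forward-simulation
  consistency check over 50 seeds, and the depth checks on 600 windows of
  10 kb — sizes at which every statistical check retains clear signal.
* The control panel used by the study this pipeline generalizes is quoted
  with two slightly different animal counts in its own description
  (~2,330 genomes); the count never enters the algorithm, only the panel
  membership set does.

# Known limitations

* The recessive-case expectation uses the product formula verbatim as the
  headline statistic; loop-induced dependence between parental
  transmissions is quantified only through the gene-drop diagnostic.
* The expected-case model is autosomal. For an X-linked recessive
  mutation the male hemizygous risk would differ (affected males need one
  maternal copy only); the package implements the stated autosomal-style
  computation and leaves X-linked transmission out of scope.
* Inbreeding is computed over the full recorded pedigree, with no
  generation-depth truncation.
* `filterPrivateHet` treats the panel as a site list; allele frequencies
  and panel genotype qualities are not modelled.
* The junction classifier assumes the derivative orientation of the
  flanks is known (inversion junctions are supplied with the distal flank
  already reverse-complemented) and uses exact matching — sequencing
  errors in the junction read are out of scope.
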