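# pedcase

Computational forensics for an isolated congenital disease case in a
pedigreed population.

When a single animal with a distinctive genetic syndrome — the motivating
case is hypohidrotic ectodermal dysplasia (HED) in a female dairy calf with
two unaffected parents — appears in a national herd book, the
mode-of-inheritance question can be answered quantitatively before any
sequencing: `pedcase` implements the pedigree side (kinship, inbreeding,
pedigree loops, gene dropping, expected recessive-case counts, progeny
mortality screens), the variant side (private heterozygous candidate
filtering against a control panel, protein-altering consequence counts),
the structural-variant side (breakpoint junction classification into
repair-mechanism signatures, dotplot word matching, read-depth
copy-number checks), and the histology quadrat morphometry that quantifies
the phenotype. It is written for geneticists curating rare-disease case
reports in livestock or other deep-pedigree populations.

A synthetic-data module generates looped pedigrees with planted carrier
ancestors, variant tables with planted private candidates, junction
sequences with configurable repair signatures, and depth profiles — so the
entire pipeline is testable against known ground truth without any
external database.

## The statistics at the core

* **Kinship / inbreeding** by the tabular recursion in topological order
  (equivalent to the row-wise Cholesky construction of the kinship
  matrix): `phi(i,i) = (1 + F_i)/2`, `phi(i,j) = (phi(s_i,j) +
  phi(d_i,j))/2`, `F_i = phi(s_i, d_i)`; validated against Wright's
  path-counting coefficient `sum (1/2)^(n1+n2+1) (1 + F_A)` to 1e-12.
* **Ancestral contribution** `c(i)`: the expected fraction of `i`'s
  genome descending from a putative carrier ancestor, by exact recursion
  `c(i) = (c(s_i) + c(d_i))/2` and by Monte-Carlo gene dropping (compiled
  core, seed-reproducible).
* **Recessive-case expectation**: `p_homo(i) = c(s_i) c(d_i) / 4` summed
  over calves per birth year; the Poisson probability `exp(-lambda)` of
  observing zero cases turns "no other case was ever reported" into a
  rejection of recessive inheritance. A joint gene-drop estimator
  quantifies the dependence the product formula ignores.
* **Junction classification**: seed-and-extend anchoring of a
  junction-spanning sequence onto its two flanks; duplicated or
  microhomologous bases at the join of length >= 2 give an MMBIR-like
  label, short deletions/insertions an NHEJ-like label, an exact join is
  blunt.
* **Copy-number neutrality**: mean depth of 10-kb windows inside vs
  outside an interval, with masked regions excluded.

## Worked example

```r
library(pedcase)

## a looped pedigree of the kind behind an isolated case: 10 ancestors
## planted in both parental lineages of the proband
sim <- simulatePedigree(nFounders = 40, nGenerations = 3,
                        loopAncestors = 10, seed = 2014)
ped <- sim$pedigree
proband <- sim$truth$proband

loops <- commonLineageAncestors(ped, proband)
length(loops)                        # 10
inbreedingCoefficient(ped, proband)  # 0.024

yr <- range(pedigreeTable(ped)$birth_year)
ces <- lapply(loops, function(a) expectedCases(ped, a, yr))
assessInheritance(ped, proband, ces, observedOtherCases = 0)
#> Inheritance assessment for proband CASE
#>   inbreeding: proband F = 0.0240, birth-cohort mean F = 0.0240
#>   common-lineage ancestors (pedigree loops): 10
#>   expected recessive cases: min 7.63e-06, max 0.0313 over 10 ancestors
#>   P(0 observed cases | min expectation) = 1
#>   recessive plausible: TRUE
#>   verdict: recessive_plausible
```

On this 144-animal toy pedigree the expected recessive-case counts are
tiny, so a recessive mutation cannot be excluded — exactly the right
answer at this scale. On a national-database pedigree the same sums reach
tens to tens of thousands of expected cases per carrier ancestor, the
zero-observation probability collapses, and the verdict flips to a de
novo dominant mutation.

The sequence side, on the printed breakpoint coordinates and a junction
reconstructed around the 12-bp motif:

```r
jx <- simulateJunction(motif = "GTACAAGAAACT", seed = 7)
classifyJunction(jx$refLeftFlank, jx$refRightFlank, jx$junctionSeq)
#> JunctionCall: MMBIR_like
#>   duplicated: 12 bp (5'-GTACAAGAAACT-3')
#>   deleted: 0 bp
#>   inserted: 0 bp

inversionLength(Breakpoint("X", 82271052), Breakpoint("X", 86034441))
#> $bp
#> [1] 3763389
#> $mb
#> [1] 3.8
```

And the skin morphometry, from the quadrat measurements shipped in
`inst/extdata/hed_quadrats.csv`:

```r
q <- readQuadrats(system.file("extdata", "hed_quadrats.csv",
                              package = "pedcase"))
quadratSummary(q)
#>      group mean_hair_count mean_diameter_um mean_total_area_um2
#> 1  control             9.3             87.2               58416
#> 2 affected            47.7             21.6               17974
foldChanges(quadratSummary(q))[c("hair_count_fold_int", "diameter_fold_int")]
#> $hair_count_fold_int  [1] 5
#> $diameter_fold_int    [1] 4
```

The affected animal has five times the hair-follicle density and pilary
canals four times narrower than the control — the quantitative signature
of the syndrome.

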