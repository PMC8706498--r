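---
title: "Diagnosing natural hybrids from mitochondrial and nuclear Sanger markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing natural hybrids from mitochondrial and nuclear Sanger markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridiag)
```

## The problem

Closely related, co-occurring species occasionally hybridise in the wild.
When a field-collected specimen looks morphologically intermediate between
two candidate parental species, a small panel of unlinked molecular
markers can settle the question without any genome-scale data:

* **Nuclear loci.** If the two parental lineages carry *fixed* nucleotide
  differences at some positions of a sequenced fragment — every individual
  of lineage A has one base, every individual of lineage B another — then
  a first-generation (F1) hybrid must be heterozygous at every one of
  those diagnostic positions. In direct Sanger sequencing of a diploid
  PCR product this heterozygosity is visible as dual peaks in the
  electropherogram and is recorded as a two-base IUPAC ambiguity code
  (`R` = A/G, `Y` = C/T, and so on).
* **A mitochondrial locus.** Animal mtDNA is maternally inherited, so the
  mitochondrial haplotype of a confirmed hybrid identifies the species of
  its mother, i.e. the direction of the cross.
* **Cloned alleles.** Direct-sequence ambiguity codes alone cannot show
  that the two underlying alleles are the two *parental* variants (rather
  than, say, within-species polymorphism). Molecular cloning of the PCR
  product isolates single template molecules; sequencing ~10 clones per
  gene should yield two clone groups matching the two parental alleles.

`hybridiag` implements this workflow as a reusable, testable pipeline:
haplotype collapsing and variable-site tables, fixed-difference discovery,
zygosity scoring, mitochondrial lineage assignment, clone phasing,
uncorrected p-distances with a bootstrap standard error, a categorical
hybrid verdict, and a synthetic-data generator with ground truth.

## The statistics and decision rules

### Haplotypes and variable sites

Sequences within a pre-aligned locus are collapsed by *literal* string
identity (ambiguity codes and gaps are not expanded). The variable-site
table lists exactly the alignment columns at which the collapsed
haplotypes disagree, 1-based, in ascending order — the compact "Table of
variable sites" format standard in barcoding papers. Haplotype labels are
`<group prefix><2-digit counter>` in order of first appearance within each
group; a query sample whose sequence equals a parental haplotype inherits
the parental label, and a label-override map supports bespoke names for
hybrid-only haplotypes.

### Fixed differences

A column is a diagnostic site when it is monomorphic for an unambiguous
base within *each* parental group and the two groups' bases differ.
Fixedness is absolute: a single discordant individual, or any ambiguity
code inside a parental group (evidence of intra-individual
heterozygosity), disqualifies the column. There is deliberately no
frequency threshold — a site that is merely *nearly* fixed cannot support
the all-heterozygous F1 argument.

### p-distance

The uncorrected p-distance between two aligned sequences is the
proportion of compared sites at which they differ. Columns where either
sequence carries a gap or any ambiguity code are deleted pairwise from
numerator and denominator (the conservative convention; consensus
heterozygote codes are genotype calls, not point observations, and should
not count as matches or mismatches). The overall mean is the average over
all unordered sample pairs; a between-groups mode averages over parental
A × B pairs only. The standard error is estimated by bootstrap over
alignment columns (default 1000 replicates, seed required), the standard
convention for p-distance SEs; the method and seed are recorded in the
output rather than left implicit. Report output rounds percentages to one
decimal; internal values keep full precision.

### Mitochondrial assignment

A query's mitochondrial sequence is compared to every parental haplotype
by Hamming distance with the same pairwise-deletion rule. The assignment
records the nearest haplotype (ties broken toward table order), the
lineage of that haplotype, and the *margin* — the absolute difference
between the nearest-A and nearest-B distances. A zero margin yields
`ambiguous`: the maternal direction of a cross is never fabricated from a
tie.

### The hybrid verdict

Nuclear loci with at least one diagnostic site are *informative*; loci
without fixed differences are reported but carry no evidence either way.
With the default `min_het_fraction = 1`, a sample is called
`f1_consistent` when every informative locus is heterozygous for the two
parental states at **all** of its diagnostic sites with no `other` call
(no-calls, gaps, or unexpected bases); `parental_A_like`/`parental_B_like`
when every informative locus is entirely homozygous for one parent's
states; `inconclusive` otherwise. The threshold is exposed because the
expected heterozygous fraction at diagnostic sites is 1 only for F1s;
lowering it permits exploratory screening for later-generation hybrids,
but that is explicitly weaker evidence and not the default claim. The
verdict label is "F1-consistent", not "F1": with a handful of diagnostic
sites, full heterozygosity cannot exclude, say, an F1 × F1 offspring that
happens to be heterozygous throughout. The maternal parent is copied from
the mitochondrial lineage only for `f1_consistent` samples.

### Clone phasing

Clones are assigned to `allele_A`/`allele_B` by majority vote over the
diagnostic sites only; full-sequence clustering is deliberately avoided so
that PCR and cloning point errors at non-diagnostic positions cannot
perturb the assignment and the rule stays auditable. A tie, or a mismatch
fraction against the winning state vector above `max_mismatch_fraction`
(default 0.49, i.e. strict majority), leaves a clone `unassigned`. The
phasing is *consistent* with the direct sequence when, at every diagnostic
site, the IUPAC expansion of the consensus symbol equals exactly the set
of bases observed across the clone-group consensuses.

## The synthetic-data generator

Real specimens cannot ship with a package, so every stage is exercised
against `simulate_hybrid_data()`, whose **defaults are the study design
the pipeline targets**: four loci (a 658 bp mitochondrial fragment with 4
fixed differences, nuclear fragments of 403 and 445 bp with 2 fixed
differences each, and a 610 bp nuclear fragment with none), 12 parental-A,
15 parental-B and 3 hybrid samples, maternal lineage B, and 10 clones per
nuclear gene per hybrid with zero clone error. The mitochondrial B lineage
segregates at 2 extra sites, giving one common haplotype plus two rare
singletons — the skewed frequency spectrum typical of a small barcoding
sample.

The generative model is intentionally minimal: an ancestral sequence is
drawn uniformly over A/C/G/T per locus; fixed-difference positions are
drawn without replacement and mutated in lineage B; each within-lineage
polymorphic site defines one rare haplotype differing from the common one
at that single position, carried by one randomly chosen sample; hybrids
receive one random allele from each lineage per nuclear locus, with the
consensus written as the two-base IUPAC code wherever the alleles differ,
and a mitochondrial haplotype drawn from the maternal lineage; clones pick
an allele with probability 1/2 each and then mutate per site at the clone
error rate. All randomness derives from one master seed; per-locus (and
per-clone-set) substreams are derived by a stable string hash of the locus
name, so adding a locus never perturbs the draws of the others.

What the generator does **not** emulate: transition/transversion bias,
rate heterogeneity, coalescent genealogies, indels and alignment error,
base-calling noise in parental sequences, and chimeric clones. A green
end-to-end test therefore establishes that the *decision logic* is correct
under the stated assumptions, not that the pipeline is robust to every
artefact of real Sanger data.

Separately from the simulator, `fixture_table2_coi()` reconstructs a
deterministic 30-specimen mitochondrial alignment from the published
variable-site table that motivated the pipeline's defaults: the nine
variable columns carry the printed haplotype states, constant columns are
an arbitrary fixed pattern, and haplotype multiplicities are 12/14/1/2/1.
Every statistic that depends only on variable columns and multiplicities
(fixed differences, Hamming distances between haplotypes, all
p-distances) is exact on this fixture. `fixture_paper_full()` adds
*synthetic* nuclear stand-ins that mirror only the published fragment
lengths (403/610/445 bp) and diagnostic positions (213/271 and 151/334);
the actual bases are invented, since the real nuclear sequences are not
printed in any table.

## Numerical and design choices

* **Coordinates** are 1-based and inclusive everywhere, matching the
  site-numbering convention of the variable-site tables the package
  reproduces.
* **Input normalisation**: residues are upper-cased and `U` → `T` on
  read; `*` and `.` are rejected rather than silently reinterpreted;
  record order is preserved everywhere (no sorting), so outputs are
  deterministic at the byte level.
* **`N` handling**: `N` is a no-call. It is excluded from heterozygous-
  site detection by default, is never comparable in distances, and forces
  an `other` zygosity call (blocking an F1 verdict) rather than counting
  as evidence.
* **Tie-breaks**: nearest-haplotype ties across lineages give
  `ambiguous`; clone majority ties give `unassigned`; majority-consensus
  ties within a clone group break alphabetically (deterministic, and
  irrelevant at zero error).
* **Degenerate inputs**: a single haplotype yields an empty variable-site
  list (not an error); a locus with no fixed differences yields an empty
  diagnostic set and is treated as uninformative; zero comparable sites
  in a distance is an error, not a silent `NaN`.
* **Bootstrap determinism**: the SE is bit-reproducible given
  (alignment, reps, seed); with identical sequences it is exactly 0.
* **Maternal-lineage margin**: reported as a count of sites so users can
  judge how firmly the mitochondrial assignment separates the lineages
  (the packaged fixture gives margin 4 for the hybrid-only haplotype).

Two open choices deserve a note. First, whether the published "overall
mean distance" of such a study averages over all samples or only between
species is ambiguous in most papers; both modes are implemented, and on
the packaged fixture the *overall* 435-pair mean reproduces the printed
0.4% (the between-groups mean is 0.6%). Second, the method behind a
printed "SE = 0.2%" is rarely stated; the column bootstrap used here
reproduces it and is declared in the output metadata rather than asserted
to be the original method.

## Worked example

```{r example, eval = FALSE}
fx <- fixture_table2_coi()

find_fixed_differences(fx$alignment, fx$metadata)
#> <diagnostic sites> locus=COI: 4 fixed difference(s)
#>  position state_A state_B
#>        40       G       A
#>       103       T       C
#>       271       A       T
#>       361       C       T

mean_p_distance(fx$alignment, "overall", bootstrap_reps = 1000, seed = 1)
#> <p-distance> mode=overall: mean=0.4%, SE=0.2% (435 pairs)

sim <- simulate_hybrid_data(sim_params(seed = 1))
run <- run_hybrid_analysis(sim$alignments, sim$metadata, "COI",
                           clones = sim$clones)
run$verdicts$H01
#> <verdict> H01: f1_consistent, maternal parent = parental_B
```

## Known limitations

* Inputs must be pre-aligned; the package performs no alignment and no
  chromatogram (.ab1) parsing — ambiguity codes are assumed already
  called.
* The verdict is categorical. There is no genotype-likelihood model, no
  probabilistic hybrid-class assignment (F2/backcross posterior), and no
  introgression statistic; with 2–4 diagnostic sites per genome those
  would be over-modelling.
* Clone phasing assumes clones are aligned to the locus frame and does
  not detect PCR chimeras; a chimeric clone spanning diagnostic sites of
  both alleles shows up as `unassigned` only when the sites disagree.
* Distances are uncorrected by design; no substitution-model correction
  (JC/K2P/GTR) is offered, as p-distances are the convention for
  barcode-scale divergences well below saturation.
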