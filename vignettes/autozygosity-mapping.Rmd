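---
title: "Autozygosity mapping and founder-variant prioritization: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autozygosity mapping and founder-variant prioritization: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozygmap)
```

## The problem

In consanguineous families, a recessive disease allele inherited from a
common ancestor sits inside a chromosomal segment that is *autozygous*:
both copies descend from a single ancestral copy, so every variant in the
segment is homozygous. Genome-wide SNP-array genotypes reveal these
segments as long runs of homozygosity (ROH), and the union of an affected
individual's long ROH — the *autozygome* — is a small search space in
which a recessive causal variant must lie. When two or more families
segregate the same founder mutation, their autozygomes overlap on the
ancestral haplotype, and intersecting them narrows the locus further;
exome variants are then filtered down to the rare homozygous
coding/splicing candidates inside that region. `autozygmap` implements
this whole chain — simulation with identity-by-descent (IBD) ground
truth, ROH calling, cross-family haplotype sharing, and the variant
filter cascade with segregation checking — as tested, reusable
components.

## Pedigree templates and the inbreeding coefficient

Three templates mirror the family structures in which founder mutations
are typically mapped: `first_cousin` (affected child of first cousins,
one shared grandparental couple), `double_first_cousin` (first cousins
through both parental lines, two shared grandparental couples), and
`two_family_founder` (a first-cousin family and a double-first-cousin
family joined through one ancestral couple carrying the founder
haplotype).

`inbreeding_coefficient()` computes Wright's F by path counting: every
pair of ancestral paths joining the two parents through a common ancestor
A, sharing no other individual, contributes $(1/2)^{L+1}(1+F_A)$ with $L$
the number of meioses on the path. For the templates this gives the
closed forms F = 1/16 (first cousins) and F = 1/8 (double first cousins).
F is also, by definition, the expected autozygous fraction of the genome
— which is exactly what the gene-dropping simulator must reproduce, so
the pair (path counting, simulation) cross-validates both.

```{r}
ped <- build_pedigree("double_first_cousin")
inbreeding_coefficient(ped, "P1")
```

## Gene dropping and the recombination model

`drop_genes()` assigns each founder two uniquely labelled haplotypes per
chromosome and transmits them down the pedigree. Recombination follows
the Haldane model: crossover counts per meiosis are Poisson with mean
(genetic length in cM)/100 and positions are uniform in genetic distance,
with no interference. We chose Haldane deliberately: it is the simplest
model whose Poisson property makes the simulator's behaviour analytically
testable (crossover counts per 100 cM chromosome must be Poisson(1), and
the mean autozygous fraction must equal F).

The genetic map defaults to a uniform 1 cM/Mb over 22 autosomes of 50 Mb
each. This desk-scale genome keeps the expectations above exact while
holding a full two-family simulation (24 individuals, 110,000 markers)
to a few seconds; chromosome number, lengths and map density are all
configurable for larger runs. The reference problem sizes used throughout
the test suite are 500 gene-dropping replicates per template for
F-recovery, 10,000 meioses for the crossover model, 1,000 random
instances for the ROH oracle, and 100 end-to-end two-family replicates.

### Ascertainment conditioning

Families reach a mapping study because a child is affected. Under
unconditional gene dropping, the probability that the affected children
of *both* families are homozygous for the *same* ancestral allele at a
preset locus is of order $10^{-4}$, so an unconditioned simulator almost
never produces the configuration the study design presupposes. We
therefore condition on ascertainment: the template records the obligate
carrier chain (the parent-to-child transmissions through which the
founder allele must travel), and `drop_genes()` forces only the
*haplotype choice at the causal locus* in those meioses, leaving crossover
counts and positions untouched. Unaffected siblings are resampled until
not homozygous — the phenotype-consistent conditional distribution.
Everything away from the causal locus, and every unconditioned meiosis,
remains an ordinary random drop. The F-recovery checks use unconditioned
templates, so the conditioning cannot bias them.

## The SNP-array emulation

`emit_snp_genotypes()` draws marker positions uniformly at the configured
density (default 1 per 10 kb — the real array's density is not a
published quantity, so this is a documented choice, not a reproduction),
gives every founder haplotype an allele per marker with minor allele
frequency uniform on [0.05, 0.5] (array panels target common variants),
and reads each individual's genotype off its founder labels. Two noise
processes follow, each independent per call: a genotyping error that
replaces the call with one of the two wrong states (default rate 0.002)
and missingness (default 0.002). The simulator emulates marker-level
genotypes only: there is no linkage disequilibrium between markers, no
sequence reads, and no X chromosome. Passing tests therefore demonstrate
correctness of the mapping machinery under array-like noise, not
robustness to LD structure or platform-specific artefacts of real arrays.

## ROH calling

`call_roh()` defines an ROH as a maximal run of markers containing at
most `max_het` heterozygous (default 1) and `max_missing` missing
(default 5) calls, trimmed to homozygous endpoint markers, spanning at
least 2 Mb (boundary inclusive; a strict flag exists) and 50 markers.
The length is measured first-to-last marker — conservative,
marker-supported, never padded to chromosome coordinates. "Maximal" means
not extendable in either direction without violating a budget; with a
nonzero het tolerance two maximal runs may overlap, and both are kept:
`assemble_autozygome()` merges them, and the merged union is what the
downstream intersection needs. The scanner is deterministic and is
verified, over randomized instances and thresholds, against an oracle
that enumerates every marker sub-interval — the two answers must be
identical.

The het tolerance is the reason noisy long segments survive: an isolated
erroneous het call splits a run into two *overlapping* maximal runs whose
union restores the segment. Tolerances are parameters rather than
constants because the tolerance the original array analyses used is not
documented anywhere we could verify. Sensitivity is assessed per true
segment as the Jaccard index against the union of called intervals
overlapping it: a cluster of error hets can nick a called segment with a
gap of a few tens of kb without losing coverage, and the union measure
reflects what the caller actually recovered. At the default noise
settings, true segments of at least 3 Mb are recovered at Jaccard at
least 0.9 in about 97% of replicates.

## Haplotype sharing across families

Intersecting autozygomes finds where affected individuals are *all*
homozygous, but coincidentally overlapping ROH are common — each family's
own consanguinity contributes private autozygosity. The decisive evidence
for a founder mutation is allele-level identity.
`check_haplotype_identity()` counts, over an interval, the markers at
which all individuals are homozygous and non-missing (informative) and
how many of those carry the same allele in everyone. Because an
intersected interval often extends beyond the truly shared core into
high-mismatch flanks, the verdict is based on the *refined window*: the
longest stretch of informative markers whose running mismatch fraction
stays within tolerance (default 0.02, absorbing genotyping error), found
by a longest-subarray search. An interval is `haplotype_shared` when that
window holds at least 25 informative markers and spans at least 2 Mb (the
ROH length convention); intervals with fewer informative markers are
`uninformative`, never shared. With unrelated haplotypes the expected
per-marker mismatch rate is about 0.3 under the default allele-frequency
model, so a 2 Mb window within 2% mismatch essentially never arises by
chance.

## The variant filter cascade

`run_cascade()` applies five filters in the order frequency, zygosity,
autozygome position, consequence, predictor consensus; each is a pure
predicate on the variant record, so the surviving *set* is invariant
under filter order (a tested property) while the per-step survivor
counts depend on the order. Two thresholds deserve comment:

* **Frequency.** The default keeps variants absent from all databases or
  with maximum catalogued frequency below 0.001 (0.1%); a stricter
  commonly used reading, 1e-4, is available by argument. The maximum
  across databases is used rather than a per-database rule — the
  conservative choice when databases disagree.
* **Predictor consensus.** Missense and in-frame variants need at least
  `min_damaging = 2` damaging verdicts among the tools with a verdict
  (PolyPhen/SIFT/CADD-style annotations are *consumed*, never computed;
  score-to-verdict thresholds belong to the annotator).
  Loss-of-function classes (nonsense, frameshift, splicing) bypass the
  predictor filter: predictors are calibrated for missense changes and a
  truncating allele is damaging on mechanism.

Candidates are matched across families on exact (chrom, pos, ref, alt) —
input is assumed normalized; no left-alignment is attempted. Segregation
under the strictly homozygous-recessive model requires every genotyped
affected to be homozygous alternate, every obligate-carrier parent
heterozygous, and no genotyped unaffected homozygous alternate; a variant
genotyped only in the proband is `uninformative` rather than consistent.
Compound heterozygosity, de novo and X-linked models are out of scope.

## Decoy variants and what "recovery" means

`emit_exome_variants()` plants one causal variant (absent from every
database, missense, unanimously damaging, genotypes following
founder-haplotype carriage) and decoys stratified by the filter they
fail: common, heterozygous, outside the autozygome, synonymous/noncoding,
predicted benign, non-segregating (an unaffected sibling homozygous), and
family-private survivors that vanish at the cross-family intersection —
the last two reproduce the realistic situation in which each index has a
handful of per-family survivors and segregation plus sharing do the final
work. Default counts (20/10/10/5+3/6/2/3 per class) keep the exome table
small but give every cascade step work to do. The end-to-end claim the
package tests is: in at least 95% of seeded two-family replicates the
final shared, segregation-consistent set contains the planted variant,
with median final-set size at most 3 (observed: almost always exactly 1).
The rare misses are honest ones — replicates where the shared ancestral
segment happens to be shorter than the 2 Mb ROH threshold.

## Numerical conventions and degenerate inputs

Intervals are 0-based half-open internally and in BED output; all report
text is 1-based inclusive (`chr21:43,809,418-44,828,031` style), and the
two conversions are tested as inverse bijections. Marker positions are
strictly increasing per chromosome (validated, not assumed). A zero-cM
chromosome transmits intact haplotypes; a marker density yielding zero
markers on a chromosome warns and skips it; an empty variant table runs
through the cascade yielding zeros. All randomness flows from a single
seed, recorded in output headers, and every pipeline run writes its
resolved configuration and applied thresholds beside its outputs;
identical configuration and seed give byte-identical output trees.

## Known limitations

* The simulator's marker independence (no LD) makes ROH calling slightly
  *easier* than on real arrays, where LD-induced homozygosity stretches
  require larger length thresholds; the 2 Mb default is the conventional
  guard.
* The genetic map is linear within chromosomes; real recombination-rate
  heterogeneity (hotspots, telomere effects) shortens or lengthens IBD
  segments relative to the uniform model.
* Haplotype sharing is assessed from homozygous genotypes, not phased
  haplotypes; for the strictly homozygous-recessive design this is
  sufficient, but the module deliberately does no phasing, no LOD-score
  linkage and no haplotype-age estimation.
* Variant identity requires pre-normalized VCF records; multi-allelic
  sites must be split upstream.
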