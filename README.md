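# autozygmap

Autozygosity mapping and recessive variant prioritization in
consanguineous pedigrees.

## What problem this solves

In families with consanguineous parents, a recessive disease allele
inherited twice from a common ancestor lies inside an *autozygous*
segment: a long stretch where both chromosome copies descend from a
single ancestral copy. On SNP-array data these segments appear as runs of
homozygosity (ROH) longer than ~2 Mb, and their union — the *autozygome*
— is the search space for the causal variant. When several families
segregate the same founder mutation, their autozygomes overlap on the
shared ancestral haplotype. This package, aimed at statistical and
medical geneticists, implements the complete mapping chain:

1. **Pedigree simulation with IBD ground truth** — template pedigrees
   (first cousins, F = 1/16; double first cousins, F = 1/8; two families
   joined by an ancestral founder couple), Wright's inbreeding
   coefficient by path counting
   (F = Σ over common-ancestor paths of (1/2)^(L+1)(1+F_A)),
   and gene dropping under the Haldane model (crossovers Poisson(cM/100),
   uniform in genetic distance), with ascertainment conditioning at a
   causal locus.
2. **ROH calling** (`call_roh`) — maximal marker runs with explicit
   heterozygote/missing tolerances, homozygous endpoints, ≥ 2 Mb and
   ≥ 50 markers by default; verified against an exhaustive
   sub-interval enumeration oracle.
3. **Cross-family haplotype sharing** (`intersect_autozygomes`,
   `check_haplotype_identity`) — interval intersection plus allele-level
   identity with a refined-window verdict separating a shared founder
   haplotype from coincidental ROH overlap.
4. **Variant prioritization** (`run_cascade`) — the ordered filter
   cascade frequency (< 0.001, or stricter 1e-4) → homozygous zygosity →
   autozygome position → coding/splicing consequence (synonymous and
   noncoding excluded) → in-silico predictor consensus (≥ 2 damaging
   verdicts, loss-of-function bypass), then cross-family intersection and
   segregation checking under the homozygous-recessive model.

File formats: PLINK text PED/MAP, VCF (genotypes and annotated exome
variants), 6-column pedigree PED, BED (0-based half-open) and TSV
(1-based inclusive). A thin command-line front end with subcommands
`simulate`, `roh`, `share`, `filter` and `run` is installed at
`inst/cli/autozygmap.R`.

## Worked example

Simulate a two-family founder-mutation study (24 individuals, 22
autosomes of 50 Mb, 110,000 array markers, one planted causal variant
among 62 decoys) and map it:

```r
library(autozygmap)

sim <- simulate_study(sim_config(seed = 42))
res <- map_study(sim$genotypes, sim$variants, sim$pedigree)
res$cascade
```

```
variant prioritization cascade
  F1_P1: input=63 -> frequency=43 -> zygosity=30 -> autozygome=20 -> consequence=12 -> predictions=6
  F2_P1: input=63 -> frequency=43 -> zygosity=30 -> autozygome=20 -> consequence=12 -> predictions=6
  shared across families: 3; final (segregation-consistent): 1
  final candidates: var_causal
```

Each affected individual ("index") retains a handful of private
survivors after the five per-index filters; intersecting the two
families leaves three shared candidates, and segregation (obligate
carrier parents heterozygous, unaffected sibling not homozygous) leaves
exactly the planted founder variant. The shared-haplotype report locates
the ancestral segment both patients inherited:

```r
res$share_report[, c("chrom", "shared_start", "shared_end", "shared_n_informative",
                     "shared_mismatch_fraction", "verdict")]
```

```
  chrom shared_start shared_end shared_n_informative shared_mismatch_fraction          verdict
1 chr21     20893413   28327254                  665              0.001503759 haplotype_shared
```

The verdict `haplotype_shared` means the two patients carry identical
homozygous alleles (here 1 mismatch in 665 informative markers, within
the 2% genotyping-error tolerance) across a > 2 Mb window — the
signature of a founder mutation, as opposed to coincidentally
overlapping ROH. The planted causal locus (chr21:25,000,000 here) lies
inside this window.

The same analysis runs file-to-file with provenance:

```r
run_pipeline(run_config(seed = 42, out_dir = "demo_run"))
```

writing simulated inputs, truth BEDs, per-index ROH BED/TSV, the shared
haplotype report, cascade step counts, final candidates, a JSON summary,
the resolved YAML configuration and a run log. Reruns with the same seed
and configuration are byte-identical.

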