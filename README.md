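# refbias

Benchmarking NGS SNP genotype calls and allele-frequency estimates against
gold-standard HLA typings, with a focus on **reference mapping bias**.

## The problem

Short-read pipelines align reads to a single reference index. At highly
polymorphic loci — the classical HLA genes are the extreme case — reads
sampled from diverged haplotypes accumulate mismatches and fail to map.
Reads carrying the alternative (ALT) allele at a SNP tend to sit on more
diverged haplotypes than reads carrying the reference (REF) allele, so this
loss is asymmetric: genotypes drift toward homozygous reference and REF
allele frequencies are overestimated. Anyone using population call sets at
HLA (association studies, selection scans, frequency databases) needs to
know which sites can be trusted.

`refbias` takes (a) NGS genotypes as a VCF, (b) Sanger-derived HLA typings
(possibly ambiguous allele names) as the gold standard, (c) an allele
catalog (FASTA of ARS-exon coding sequences) and (d) an exon map
(JSON: ARS exon coordinates, strand, index sequence), and computes:

* **Genotype concordance** per site/individual, after an ambiguity
  correction that resolves gold base sets against the NGS call, with a
  strict both-alleles-present match rule;
* **Frequency error** per site and population,
  `FE_i = f_i,NGS − f_i,gold`, and per-gene `MAE = mean |FE_i|`;
* **Site classification** (overestimated `FE > 0.1`, underestimated
  `FE < −0.1`, well estimated `|FE| < 0.01`) and an **unreliable-site
  list** (`|FE| > 0.1` in ≥ 2 populations);
* an exact binomial **direction test** for REF-ward skew among flagged
  sites;
* the **mapping-bias window test**: 51-bp windows around each SNP from
  every chromosome copy, mismatches to the reference index counted
  excluding the central SNP, ALT vs REF groups compared with one-tailed
  Mann-Whitney rank-sum tests;
* **coverage** and **heterozygosity** (`H = 2p(1−p)`, gold-based)
  correlates of the error.

A synthetic-data generator produces gold + NGS datasets in the same
formats under a per-read mapping-loss model — a read with `m` mismatches to
the index survives with probability `(1−λ)^m`, and focal ALT alleles carry
`δ` linked flanking variants — so the whole pipeline is testable end to end
with no external downloads. See the methods vignette
(`vignettes/benchmarking-hla-snp-calls.Rmd`) for the model, parameter
defaults and design choices.

## Worked example

The numbered scripts under `analysis/` run the full workflow on the default
simulated scenario (930 individuals in 10 populations, three focal SNPs
with `δ = 3` linked flanking variants, `λ = 0.3`):

```sh
Rscript analysis/01_simulate.R            # write VCF/TSV/FASTA/JSON bundle
Rscript analysis/02_genotype_concordance.R
Rscript analysis/03_frequency_error.R
Rscript analysis/04_mapping_bias.R
Rscript analysis/05_coverage.R
```

Output of steps 2–4 on that scenario:

```
Overall mismatch rate: 19.9%
29.6% of sites hold 50% of all mismatches.

MAE over 71 SNPs: 0.070
Unreliable sites (|FE|>0.1 in >=2 populations): 18
Skew direction among flagged sites: 18 REF vs 0 ALT (exact binomial p = 7.63e-06)
H vs FE: r = 0.40; H vs |FE|: r = 0.40; mismatch rate vs |FE|: r = 0.92
Mean gold H: flagged 0.468 vs retained 0.386 -> filtering lowers mean H

Window mismatch means by site class (one-tailed rank-sum, ALT > REF):
  overestimated  ALT 4.26 (n=14227) vs REF 1.60 (n=11393), p = 0
  well_estimated ALT 0.60 (n=1918) vs REF 1.17 (n=7232), p = 1
```

Reading this: a fifth of genotypes disagree with the gold standard, but the
errors concentrate on a minority of sites; eighteen sites are flagged
unreliable and *all* of them overestimate the REF allele (binomial
p ≈ 8 × 10⁻⁶); at overestimated sites, windows carrying the ALT allele bear
~2.7 more flanking mismatches against the index than REF windows — the
mapping-bias signature — while well-estimated sites show no ALT excess.
Flagged sites are the high-heterozygosity ones, so filtering them deflates
diversity estimates; that trade-off is exactly what the flag list is for.
Step 5 shows mismatched genotypes sitting at lower surviving-read depth
(1.94× vs 4.28×): under the loss model, low coverage is a symptom of the
same read loss, not an independent cause.

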