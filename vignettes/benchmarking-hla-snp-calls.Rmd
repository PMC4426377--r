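---
title: "Benchmarking NGS SNP calls against gold-standard HLA typings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking NGS SNP calls against gold-standard HLA typings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refbias)
```

## The problem

Short-read pipelines call genotypes by aligning reads to a single reference
index. At highly polymorphic loci -- the classical HLA genes being the
extreme case -- reads sampled from haplotypes that diverge from the index
carry many mismatches and are more likely to fail alignment. Because reads
carrying the alternative (ALT) allele at a SNP tend to sit on more diverged
haplotypes than reads carrying the reference (REF) allele, this *mapping
bias* preferentially removes ALT evidence: genotypes are pulled toward
homozygous reference and REF allele frequencies are overestimated.

`refbias` benchmarks an NGS SNP call set against HLA typings obtained by
Sanger sequencing of the antigen-recognition-site (ARS) exons, treated as a
gold standard, and tests whether mapping bias explains the disagreement. It
also ships a synthetic-data generator that produces gold and NGS datasets
with exactly this error mechanism, so every stage of the pipeline is
testable end to end without any external data.

All positional analysis happens in 1-based CDS coordinates over the
concatenated ARS exons (546 bp for class I loci, exons 2+3; 270 bp for
class II, exon 2). VCF records are translated into this frame on ingest and
reverse-complemented for loci on the genomic minus strand.

## From allele names to site genotypes

Gold typings arrive as HLA allele names (`B*35:03`), possibly as
`/`-separated ambiguity lists (`B*35:02/B*35:03/B*35:04`). Each call is
expanded against an allele catalog (FASTA of ARS coding sequences keyed by
full allele names) into a **consensus sequence**: at each CDS position, the
set of bases observed across all candidate sequences. A lower-resolution
name (fewer numeric fields) contributes every catalog entry that shares its
leading fields, exactly like an explicit ambiguity list. Names carrying
expression suffixes (N, L, ...) are rejected rather than guessed at.
Unanimous positions are singletons; disagreements become sets such as
`A/T`. The two per-copy consensus sequences are then deconstructed into
per-site genotypes whose alleles are base *sets* (gold) or single bases
(NGS).

Two rules govern the comparison:

* **Correction.** An ambiguous gold base set that intersects the NGS allele
  pair is resolved to a base from that intersection (when both copies are
  ambiguous, the assignment that maximises the subsequent match is chosen;
  remaining ties resolve to the alphabetically first base, a neutral,
  deterministic choice). Sets disjoint from the NGS pair are left as they
  are.
* **Match.** After correction, a comparison is a match only if the NGS
  alleles can be paired one-to-one with the gold copies, each NGS base
  belonging to its paired copy's set. The pairing semantics matter for
  homozygous calls: NGS `(A, A)` against gold `({A}, {T})` is a mismatch,
  because the second `A` has no gold copy left to account for it.

Correction is applied per site independently. A typing ambiguity that spans
several sites jointly (different allele *pairs* compatible with the
sequencing) is thereby relaxed site by site; the package treats each
reported copy independently, which can resolve a joint ambiguity into a
combination no single candidate allele pair carries. This is a known
simplification, shared with any per-site treatment of the data.
Individuals with missing NGS genotypes at a site are excluded from that
site's comparisons and from both frequency denominators -- the conservative
reading when the call set gives no evidence either way.

## Frequency error statistics

For site $i$, with $f_{i,\mathrm{NGS}}$ and $f_{i,\mathrm{gold}}$ the REF
allele frequencies in the two datasets (gold after correction),

$$\mathrm{FE}_i = f_{i,\mathrm{NGS}} - f_{i,\mathrm{gold}}, \qquad
\mathrm{MAE} = \frac{1}{n}\sum_{i=1}^{n} |\mathrm{FE}_i|.$$

Residual gold ambiguity (sets the NGS pair could not resolve) contributes
fractionally -- $1/|\mathrm{set}|$ of a REF allele when REF is in the set --
which avoids pushing the gold frequency in either direction. Frequencies
are computed per population and for the pooled set of all individuals
("global", unweighted pooling).

Sites are classified by their pooled FE: *overestimated* (FE > 0.1),
*underestimated* (FE < -0.1), *well estimated* (|FE| < 0.01), else
*intermediate*. A site is **flagged unreliable** when |FE| > 0.1 in at
least two populations, a criterion robust to a single population's
sampling noise. Among flagged sites, an exact two-sided binomial test
(null: probability 0.5) asks whether deviations skew toward REF
overestimation; each flagged site is given the sign of its *pooled* FE.
(Whether a site should instead be signed by its majority direction across
populations is not determined by the data model; pooled sign is the
default because the pooled estimate has the smallest variance, and the
per-population table is written out so either convention can be applied.)

Downstream correlates use sample heterozygosity $H = 2p(1-p)$ computed
from the **gold** frequencies only, so that any association between $H$
and FE reflects true diversity at the site rather than NGS error;
correlations (H vs FE, H vs |FE|, per-site mismatch rate vs |FE|, mean
coverage vs |FE|) are Pearson correlations with two-sided t-based
p-values.

## The mapping-bias window test

For every SNP, a window of up to 51 bp (25 bp each side, truncated at the
CDS boundaries rather than padded with invented sequence) is taken from
*each chromosome copy* of every typed individual -- 2 windows per
individual, e.g. 1860 windows for a 930-sample cohort. Windows are split
by whether the copy carries REF or ALT at the central site, and each is
compared with the index (reference genome) sequence, counting mismatches
but **excluding the central site itself**. Copies still ambiguous at the
central site after correction belong to neither group and are dropped; an
ambiguous flanking position counts as a match when the index base is in
its set, else as one mismatch. Windows may span the exon-2/exon-3 junction
in class I loci because the allele sequences and the site numbering live
on the concatenated CDS; the genomic gap between the exons is not
represented, which slightly overstates the contiguity of the flank a real
read would see.

Within each site class, ALT windows are compared with REF windows by a
one-tailed Mann-Whitney rank-sum test (alternative: ALT windows carry more
mismatches). The implementation enumerates all group assignments exactly
whenever $\binom{n_a+n_b}{n_a} \le 2\times10^5$ -- which covers the exact
small-sample regime and handles ties correctly -- and otherwise uses the
normal approximation with midranks, tie-corrected variance and a 0.5
continuity correction.

### What the window counts can and cannot support inferentially

Copy-weighted windows reproduce the field's reporting convention and are
what the per-site and per-class summaries show. They are, however,
duplicates of at most a few dozen distinct haplotypes, so a rank-sum test
that treats them as independent observations wildly overstates its
effective sample size; its p-values are best read as descriptive. The
same caution applies one level deeper: allele catalogs contain families
of near-identical alleles (synonymous and noncoding variants of a common
founder), and family members share both their central allele and their
flanking content. The unit that is actually exchangeable under the
"no-bias" null is the founder lineage. The package's calibration studies
therefore run the test on one representative haplotype per lineage
(`simulate_and_benchmark()`), and at that unit the type-I error rate is at
its nominal level, as the test suite verifies by simulation.

## The synthetic-data generator

`sim_config()` + `simulate_dataset()` produce a complete gold + NGS
dataset from one seed (byte-identical files on re-runs). The generator is
deliberately the *minimal* model that produces reference mapping bias:

1. **Pool.** A uniform-random reference ARS sequence of length $L$;
   background biallelic sites at density `snp_density`, each with an ALT
   carriage probability drawn from U(0.1, 0.5) so per-site frequencies
   span a realistic range; about 30% of the `n_alleles` pool alleles are
   derived copies of another allele (1-2 differences), mimicking the fine
   structure of HLA nomenclature and providing partners for ambiguous
   typings. At each configured **focal site**, ALT-carrying alleles also
   carry `delta` shared extra variants within the read span -- the linkage
   between a focal ALT allele and additional flanking differences that
   drives mapping bias.
2. **Populations.** Per-population allele frequencies are symmetric
   Dirichlet draws over the pool; individuals sample two alleles
   independently. With probability `ambiguity_rate` a gold call becomes an
   ambiguity set (true allele plus a catalog allele within 2 differences),
   and with probability `missing_rate` the typing is absent.
3. **Reads and calls.** For each genotyped site, each chromosome copy
   contributes $\mathrm{Poisson}(c/2)$ reads spanning the window around
   the site. A read whose haplotype has $m$ mismatches to the index within
   that span survives alignment with probability $(1-\lambda)^m$ -- here
   the central site *does* count, since a mapper does not know which site
   the analyst will focus on (the analysis-side window statistic excludes
   it; the asymmetry is intentional). Surviving reads report the copy's
   base, miscalled to a random other base with probability `epsilon`. The
   genotype is the maximum-likelihood diploid genotype over {REF, ALT}
   under the symmetric read-error model; exact likelihood ties resolve in
   the order hom-REF, het, hom-ALT, and an individual with zero surviving
   reads is emitted as homozygous REF by default (`zero_read_call`),
   mimicking integrated, imputation-backed call sets that report a
   genotype everywhere and default to the reference in the absence of
   evidence; set `zero_read_call = "missing"` for sensitivity analyses.

Default parameters, chosen once as the package's standard study
conditions:

| parameter | default | why |
|---|---|---|
| `L`, `class` | 546, I | class I ARS CDS (exons 2+3: 270 + 276) |
| `n_alleles` | 60 | HLA-scale allelic richness; ~18 derived alleles |
| `n_populations` x `n_individuals` | 12 x 78 | a ~930-sample, 12-population cohort, the scale of the real gold-standard panel |
| `snp_density` | 0.12 | gives REF-window flank mismatch means near 2 over 51 bp, the level seen at real class I loci |
| `focal_sites` | 132, 244, 400; `delta` = 3 | three well-separated focal SNPs; ALT haplotypes carry 3 linked flanking variants |
| `concentration` | 1 | flat Dirichlet: population frequencies vary widely |
| `mean_depth` | 8 | nominal pre-alignment depth in the low-coverage WGS range; surviving depth drops toward ~2 at heavily mismatched windows once `lambda` acts |
| `half_width` | 25 | 51-bp read span / analysis window |
| `lambda` | 0.3 | per-mismatch read-loss rate: strong but not total bias |
| `epsilon` | 0.005 | per-read base-call error |
| `ambiguity_rate`, `missing_rate` | 0.1, 0.02 | typical typing-ambiguity and dropout levels |

What the generator does **not** emulate -- and hence what passing tests do
not show about real data: coalescent genealogies (alleles are star-shaped
around the reference plus two-level families); paralogous gene copies and
multi-mapping reads (a second, HLA-relevant loss channel); realistic
fragment lengths, quality scores or indels; cross-sample imputation and
LD-aware genotype refinement (real integrated call sets borrow information
across individuals; the zero-read fallback is a crude stand-in for that
behaviour); and joint multi-locus typing ambiguity.

## Numerical and degenerate-input choices

* Exact rank-sum enumeration switches to the normal approximation when the
  assignment count exceeds 2e5; group sizes are taken to double precision
  before forming $n_a n_b$ (integer overflow territory above ~46k each).
* All-tied rank-sum input returns p = 1 (no evidence of a shift).
* `ref_allele_frequency`, `mae`, `mismatch_summary`,
  `mismatch_concentration` and the Pearson helpers reject empty or
  constant inputs loudly instead of returning NaN.
* `mismatch_concentration` takes sites in descending count order and
  returns the minimal fraction of sites whose counts reach the requested
  mass; ties in counts cannot change the result.
* p-values are reported as computed, down to floating-point underflow; no
  artificial floor is imposed.
* Sites present in the VCF but monomorphic in the gold data are still
  compared (the gold contributes its fixed base): the benchmark covers
  whatever the call set reports.

## Problem sizes used by the test suite

The simulation studies in the test suite use 200-individual cohorts
(2 populations) with 200 replicates for the null calibration (mean focal
FE within 3 Monte-Carlo SE of zero; lineage-level rank-sum rejection rate
in [0.03, 0.07] at $\alpha = 0.05$), 100 replicates for mechanism recovery
(focal sites flagged overestimated; window differential within 0.5 of
`delta`; positive H-FE correlation) and 100 replicates per point of the
$\lambda \in \{0, 0.1, 0.3, 0.6, 1\}$ dose-response grid. These sizes keep
the whole suite in the minutes range while leaving the Monte-Carlo error
well inside the asserted bands.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, n_individuals = 93, n_populations = 10)
sim <- simulate_dataset(cfg)
r <- run_locus_pipeline(sim$gold, sim$ngs, sim$pool$catalog,
                        sim$pool$locus, depth = sim$depth)
summarise_results(list(A = r))
```

The analysis workflow under `analysis/` (steps 01-05) runs this scenario
end to end through the on-disk formats, and `scripts/acceptance.R`
recomputes the headline quantities from scratch; see the README.

## Limitations

The benchmark quantifies disagreement with a gold standard that is itself
an assay of limited resolution: typing ambiguity is modelled, Sanger
errors are not. The correction rule deliberately gives the NGS data the
benefit of the doubt at ambiguous gold sites, so reported mismatch rates
are a lower bound on true discordance. Flagging thresholds (0.1, 0.01,
two populations) are conventions, exposed as parameters. Finally, the
generator's bias mechanism is a single-index mapping-loss model; real
pipelines add paralogy, imputation and caller-specific behaviour that this
package intentionally leaves out of scope.
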