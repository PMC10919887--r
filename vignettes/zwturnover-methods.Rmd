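---
title: "Methods: simulating sex-determining mutation turnover on undifferentiated ZW chromosomes"
author: "zwturnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating sex-determining mutation turnover on undifferentiated ZW chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zwturnover)
```

## The biological model

Several fish lineages determine sex through a single segregating variant in
an otherwise undifferentiated chromosome pair: females are heterogametic
(ZW), males homogametic (ZZ), and the only consistent difference between Z
and W is the sex-determining variant itself. `zwturnover` models the
microevolution of such a system when the sex determiner is a single gene
whose *functional* allele is dominant and feminizing:

1. a chromosome carrying a fully functional copy of the gene behaves as W;
2. any loss-of-function (LOF) change — missense, nonsense, or disruption of
   a splice dinucleotide — converts the copy to a Z;
3. an individual is female if and only if it carries at least one
   functional copy.

Nothing else distinguishes W from Z. Purifying selection on the W and
neutral evolution of the Z are therefore *emergent*: a W that acquires a
LOF mutation simply stops making females, while Z-linked copies accumulate
change without phenotypic consequence. Sporadic LOF mutation of W copies
continuously converts W chromosomes into Z chromosomes, and this is the
engine of *turnover*: the population can end up with its sex-determining
function residing at a different position of the gene than where it
started.

## The locus model

The simulated locus is a gene segment (default 1,678 bp, two exons, one
intron, roughly half coding) represented by a `gene_model`: a reference
sequence, exon intervals (0-based, half-open), the reading frame of the
spliced coding sequence, and the splice dinucleotides (GT at each intron
start, AG at each end). Every possible point mutation `(position,
alternative base)` is classified once, against the reference:

* inside a donor/acceptor dinucleotide → `splice_site` (always LOF);
* exonic → translate the reference codon with the base substituted
  (standard genetic code): `synonymous`, `missense`, or `nonsense`;
* otherwise → `intronic`.

Missense, nonsense and splice-site changes are LOF. Nonsense changes are
included although the motivating observations name missense and splice
disruption: a premature stop is at least as disruptive as an amino-acid
substitution, and the natural Z-type transcript itself gains a premature
termination codon through its disrupted donor. Classification is relative
to the *reference* codon, ignoring other segregating changes in the same
codon; this makes the effect a pure function of `(position, base)` that can
be cached as a 4 × L table, and at the mutation rates simulated here,
doubly hit codons are vanishingly rare. Back-mutation is possible (explicit
finite-sites bases, not infinite sites); a site restored to the reference
base carries no difference entry, so reversion restores function.

The real segment's exon/intron coordinates are not published, so the
default locus is generated (`generate_gene_model()`): coding sequence
assembled from sense codons (ATG start, single terminal stop), introns
opened with GT and closed with AG, exon fraction 0.5 ± 5%, founding
sex-determining mutation placed on the first intron's donor G (G→A), which
is classified `splice_site`. The exon count and coding fraction are
exposed because they set the LOF target size (with the defaults, about 38%
of all possible single-base changes, i.e. ~75% of exonic changes plus the
four splice positions) and therefore the supply rate of new
sex-determining mutations. Turnover and fixed-mutation tallies respond to
this choice; the defaults are the package's fixed study conditions.

## The Wright–Fisher engine

Populations hold `2N` chromosomes in `N = 2N/2` diploids with
nonoverlapping generations. The initial state segregates exactly one
mutation: `⌈N/2⌉` females W/Z and the remaining males Z/Z, where every Z
carries only the founding splice-donor change.

Each offspring draws a mother uniformly from the females and a father
uniformly from the males (with replacement) and receives one gamete from
each. A gamete is formed by:

1. **Recombination.** The parent's homologs differ at `d` sites (the raw
   pairwise difference count). The per-site recombination rate is
   `r = r0 · max(0, 1 − c·d)` with `c = 0.03` per difference: each
   difference suppresses 3% of baseline recombination, reaching complete
   suppression at `d ≥ 34`. With probability `min(1, L·r)` a single
   crossover at a uniform internal breakpoint joins the left part of one
   homolog to the right part of the other; otherwise one homolog is copied
   (probability ½ each). The printed form of this rule in the motivating
   work is ambiguous ("r0 × (1% to 3% × d)"); the package reads it as the
   explored suppression coefficient range with 3% selected, because this
   reading recovers `r = r0` for undiverged homologs — the
   undifferentiated-chromosome premise — and yields progressive suppression
   with divergence. `c` is configurable in [0, 1] so the alternative
   reading can be explored. A Poisson multi-crossover mode exists but is
   off by default: at the simulated rates the probability of two crossovers
   is below (1.7 × 10⁻³)².
2. **Mutation.** Poisson(`mu · L`) point mutations at uniform positions,
   each to a uniformly chosen base among the three alternatives to the
   current base.

Sex of the offspring follows from functionality of its two gametes. There
is no fitness component, no demography, and no selfing constraint beyond
the sexes of the parents. If a generation contains no females or no males
the replicate stops with status `extinct_single_sex` (recorded, not an
error); at `2N = 100` this has probability ≈ 2⁻⁵⁰ per generation and is
never observed in practice.

Two implementations share this specification: a naive per-individual R
engine (`engine = "r"`), written to be audited line-by-line, and the
default compiled engine (`engine = "cpp"`) holding haplotypes as sparse
sorted difference vectors with per-parent divergence caching. The test
suite checks them against each other in distribution (two-sample tests on
sex ratio, π_all and segregating-site counts over 200 replicates at
`2N = 20`, 500 generations). Both draw all randomness from R's RNG, so a
`(params, seed)` pair reproduces a replicate bit-identically within an
engine (the two engines consume the RNG stream differently and are only
distributionally equivalent). Batch replicate `i` uses seed
`base_seed + i − 1`.

An `autosomal = TRUE` mode draws both parents sex-blind; it exists for
neutral-drift calibration (a neutral marker at initial frequency `p` must
fix with probability `p`), not for study runs.

## End-state census and turnover

At the end of a replicate every chromosome is classed W (functional) or Z
(LOF). LOF-classified positions carried by Z chromosomes are partitioned
into **fixed** (on every Z) and **nonfixed** (on some but not all); a
position with two different alternative bases counts once, and "fixed"
refers to the Z class because a W cannot, by definition, carry a LOF
change. A **turnover** is scored when the final state has exactly one
fixed LOF position, that position differs from the founding site, and no
nonfixed LOF segregates — i.e. the sex-determining function has moved,
cleanly. Batches aggregate into the standard summary: TS (% of replicates
with a turnover) and histograms of replicates by fixed (0–3, 4+) and
nonfixed (0–4, 5+) counts.

Diversity statistics are difference *counts per segment* (not per site,
matching how the motivating analysis reports them; per-site scaling is a
flag): π within the whole population, the W class and the Z class; d~xy~
as the mean difference count over W×Z cross pairs; and
F~st~ `= 1 − ((π_w + π_z)/2)/d_xy`, undefined when d~xy~ = 0. The
allele-count implementation is exactly equivalent to the double loop over
pairs and is tested against it. One subtlety: for two *identical* groups
the cross-pair mean includes self pairs, so F~st~ evaluates to `−1/(n−1)`
rather than 0; this is a property of the estimator, asserted exactly in
the tests.

## Association statistics

The small confirmatory statistics around a candidate sex-determining
variant are included:

* `genotypic_sex_association()`: Pearson chi-square without continuity
  correction; the default collapses genotypes to heterozygous vs
  homozygous (2 × 2, df = 1), the natural test of a ZW pattern. For a
  perfectly sex-linked variant the statistic equals the sample size: 45
  heterozygous females vs 37 homozygous males gives χ² = 82,
  p = 1.36 × 10⁻¹⁹; 14 vs 7 gives χ² = 21, p = 4.56 × 10⁻⁶ (the printed
  reference value 4.5 × 10⁻⁶ is within 2% of the closed form; whether it
  was truncated or produced by a slightly different test variant cannot be
  determined, and the package documents the closed-form value). The full
  three-genotype df = 2 test is an option.
* `heterogamety_pattern()`: ZW_like / XY_like / none from genotype-by-sex
  data.
* `sex_ratio_chisq()`: 1-df test against 1:1.
* `windowed_pi()` and `depth_log_ratio()`: 10-kb nonoverlapping window
  diversity from allele frequencies (`2p(1−p)·n/(n−1)` summed per window)
  and `log2((male + 0.1)/(female + 0.1))` coverage ratios, the two
  genome-scan summaries used to establish that sex chromosomes are
  undifferentiated.

## Synthetic data

`generate_sex_genotype_cohort()` builds cohorts with one causal variant in
perfect ZW linkage (females heterozygous, males homozygous derived) over
sex-independent Hardy–Weinberg background variants, with presets matching
the two validation cohort shapes (45 F/37 M SNP; 14 F/7 M 4-bp deletion);
`generate_coverage_tracks()` builds male/female depth tracks with a common
mean. What the generator does *not* emulate: linkage disequilibrium among
background variants, genotyping error, related individuals, or read-level
noise — so passing tests demonstrate the statistics and the generator's
contracts, not robustness to those real-data complications.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere except the VCF boundary
  (1-based POS).
* Breakpoints are uniform on the L−1 internal boundaries; `d` is a raw
  count (a proportion would make `0.03·d` negligible and the clamp
  unreachable).
* The census of an empty Z class is valid (no LOF sets, no turnover);
  groups of size < 2 give `NA` diversity rather than an error.
* Seeds: every generator takes an explicit integer seed and restores the
  caller's RNG state; batches derive replicate seeds additively.
* Problem sizes used by the shipped test suite were chosen as desk-scale
  study conditions: the two `2N = 100` parameter sets run at full scale
  (100 replicates × 100,000 generations); the large-population contrast
  runs at `2N = 1,000` vs `2N = 100`, 50 replicates, 20,000 generations
  (the standing number of segregating LOF lineages is stationary well
  before that horizon, so longer runs do not change the contrast). Full
  `2N = 10,000` runs are supported but take hours per set.

A caution on the scaled-down large-population contrast: the expected
number of co-segregating nonfixed LOF lineages grows roughly like
`N · u_LOF · log N`, so at `2N = 1,000` the excess over `2N = 100` is
real but small (a few percent of replicates vs none), and a 50-replicate
one-sided two-proportion test does not generally reach α = 0.01 at this
scale — the suite asserts both the direction and the significance
threshold, and the latter can fail for this intermediate population size
even though the same scaling puts the full `2N = 10,000` conditions at
tens of percent, in line with full-scale expectations.

## Known limitations

* Single-locus, single-gene determination; no X/Y (male-heterogametic)
  mode, no selection coefficients, no demography.
* Classification against the reference codon ignores epistasis between
  two segregating changes in one codon (negligible at study mutation
  rates, wrong in principle at very high `mu`).
* "W/Z" class is defined by current functionality, not ancestry; a
  haplotype that regains function by back-mutation re-enters the W class.
* The locus architecture is synthetic; quantitative tallies (TS, fixed
  counts) depend on the exon fraction through the LOF target size, so
  they are comparable across runs of this package but only approximately
  anchored to any particular real gene.
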