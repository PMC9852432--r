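---
title: "Phosphosite scanning: models, assumptions and numerical choices"
author: "PhosphoScan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phosphosite scanning: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhosphoScan)
```

## The problem

CDK substrates are commonly phosphorylated on clusters of minimal S/T-P
consensus sites inside disordered regions, and for most substrates it is
unknown which of the many sites carry regulatory function. Phosphosite
scanning addresses this by brute force: every site in a
multisite-phosphorylated domain is fixed to one of a small set of states —
wild type (`W`, the S/T-P motif retained), unphosphorylatable (`A`, the
phosphoacceptor replaced by alanine, proline retained) or phosphomimetic
(`E`, the whole S/T-P pair replaced by two glutamates to mimic the charge of
a phosphate) — in **all combinations**, and the resulting mutant pool
competes in one culture through a serial-dilution time course. Allele
frequencies are read out by paired-end amplicon sequencing, and each
mutant's fitness, a proxy for protein activity, is summarized by a selection
coefficient. The model system is the transactivation domain (TAD) of the
yeast transcription factor Hcm1, with eight CDK sites; its two-state
libraries over eight sites have $2^8 = 256$ members.

## The selection-coefficient model

Let $c_{g,r}(t)$ be the read count of genotype $g$ in replicate $r$ at time
$t$ (hours) and
$f_{g,r}(t) = (c_{g,r}(t) + \mathrm{pc}) / \sum_h (c_{h,r}(t) + \mathrm{pc})$
its pseudocounted read fraction. Per replicate, an unweighted OLS line is
fit to $\log_2 f_{g,r}(t)$ against $t$ over **all** timepoints, and the
selection coefficient is the slope relative to the reference allele:

$$\mathrm{SC}_{g,r} = \widehat{\beta}_{g,r} - \widehat{\beta}_{\mathrm{ref},r},$$

so $\mathrm{SC}_{\mathrm{ref}} \equiv 0$ exactly in every replicate, mutants
less fit than the reference are negative, fitter mutants positive.
Replicates are fit independently and then averaged. Units are log2
fractions per hour: with 12-h sampling over 72 h this is the scale on which
screen effect sizes of a few times $10^{-2}$/h are typically reported.

Two algebraic identities are load-bearing and are verified numerically in
the test suite:

* because OLS is linear, the difference of slopes equals the slope of the
  per-timepoint difference, so the nonlinear $-\log_2 \sum_h$ normalizer
  cancels exactly between mutant and reference — with noise-free input the
  estimator returns the true $s_g$ to machine precision;
* the SC equals the OLS slope of the corresponding row of the enrichment
  matrix
  $E_g(t) = [\log_2 f_g(t) - \log_2 f_g(0)] - [\log_2 f_\mathrm{ref}(t) - \log_2 f_\mathrm{ref}(0)]$,
  the heatmap quantity, whose $t = 0$ column and reference row are zero by
  construction.

**Pseudocount.** Published screen analyses are typically silent about
zero-count handling. The default here is a symmetric pseudocount of 0.5
added to every genotype at every timepoint, which keeps $\log_2$ finite,
preserves depth invariance up to a vanishing correction, and is
configurable (including 0, used in the exactness tests where counts are
strictly positive). Genotypes entirely absent from a sample are treated as
zero counts rather than missing data.

**Reference in the pool.** For the W-containing libraries the all-W
genotype is a library member; for the fixed-state A/E libraries the
reference allele (wild type, or the stabilized *hcm1-3N* allele for the 3N
background screen) is spiked into the pool as an extra member, and
`poolGenotypes()` returns library plus reference (257 members for the A/E
screen).

## The synthetic-data generator

`competitionModel()`/`simulatePool()` implement a pooled serial-dilution
competition with a deterministic expectation layer,

$$N_g(t + \Delta t) = N_g(t)\, 2^{(r_0 + s_g)\,\Delta t},$$

and optional, independently seeded stochastic layers: one multinomial draw
of the initial pool (the pre-selection outgrowth), a multinomial bottleneck
at every dilution, and multinomial sampling of the sequencing depth at
every timepoint. Fitness is parameterized directly in log2-fraction-slope
units so simulator inputs and pipeline outputs share one scale; the
reference growth rate $r_0$ cancels from every SC and defaults to 0.25
doublings/h (a ~2.8-h doubling, a realistic budding-yeast rate in synthetic
medium).

Frozen default conditions mirror the canonical screen design: 7 timepoints
at 0–72 h every 12 h, 3 replicates, a $10^7$-cell bottleneck, $10^6$ read
pairs per timepoint, PE150 reads. Sequencing depth per sample is not a
published quantity; $10^6$ pairs/timepoint is the fixture choice. Under
these conditions, with per-genotype fitness drawn uniformly from
$(-0.02, 0.02)$, the pipeline recovers mean SCs with RMSE well below 0.002
and rank correlation above 0.99 — the binomial sampling floor at this depth
— and recovers them exactly (to $10^{-10}$) when the stochastic layers are
disabled. The galactose-to-dextrose media switch that starts selection is
modeled simply as "selection begins at $t_0$".

What the generator does **not** emulate: PCR jackpots and chimeras,
quality-score structure, index hopping, plasmid copy-number variation and
fitness effects of the marker itself. Passing the recovery tests therefore
demonstrates correctness of the estimator under multinomial sampling, not
robustness to library-preparation artifacts in real data.

The two-strain flow-cytometry co-culture assay is the 2-genotype special
case (`simulatePairwise()`): percent composition per timepoint from a
5,000-cell binomial draw, matching common practice; `pairwiseSC()` fits the
slope of $\log_2(p_\mathrm{mut}/p_\mathrm{ref})$.

## Exact-match counting

Counting follows the published convention of counting an allele only for
read pairs with an exact sequence match in both reads. The matcher is a
joint lookup keyed on (first 150 bases of the amplicon, reverse complement
of its last 150 bases); a pair increments exactly one genotype iff both
mates match the same allele, otherwise it is discarded and tallied
(mate-1 mismatch, mate-2 mismatch, wrong length, non-ACGT characters — `N`
never matches). Conservation (assigned + discarded = total) is asserted on
every invocation. There is no trimming, no quality filtering and no fuzzy
matching: exactness is the only filter, and untrimmed read length is the
window size, since on a fixed amplicon any length variation signals
upstream problems.

**Why single errors can never misassign here.** Joint-key exactness alone
does not forbid a single sequencing error from converting one allele's
window into another's: if two alleles differed at a single base inside one
window and nowhere else in that window pair, one substitution would suffice.
The synthetic region is therefore constructed so that the wild-type codon
pairs (ACC/TCC + CCT) differ from both mutant codon pairs (GCT CCA,
GAA GAA) at two or more bases, making the minimum pairwise distance between
any two allele amplicons ≥ 2 within the covered windows. A 10,000-trial
corruption test asserts zero false assignments. Users supplying their own
region and codon map should be aware this guarantee depends on that
distance property; `buildMatcher()` always rejects outright ambiguity
(identical window pairs) at build time.

## Library realization and oligo tiling

A genotype is realized at the DNA level by replacing the two codons of each
non-W site with a fixed codon pair from the configurable `codonMap`
(defaults: `A → GCT CCA`, `E → GAA GAA`, chosen once and frozen so
genotype → DNA is deterministic and injective; real libraries vary codon
usage per oligo, which matters for neither counting nor fitness).

The tiling solver (`tileRegion()`) places `nTiles` tiles over the region
such that consecutive tiles share an overlap window inside the configured
range (default 21–27 bp, six tiles over the 270-bp region) and no
phosphosite codon falls inside an overlap — the condition for all variants
of adjacent tiles to share identical annealing flanks and assemble without
bias. Placement is deterministic: windows are placed leftmost at maximal
width, with depth-first backtracking only for global feasibility, so a
given input always yields the same plan. Assembly
(`enumerateAssemblyProducts()`) is modeled at the sense-strand level as
exact overlap-merge — the alternating-strand anneal/extend chemistry is
abstracted away because the computational content is the combinatorial
product. Overlap-mismatched combinations are excluded and counted. For the
default design the per-tile variant counts (1, 2, 4, 2, 2, 8) multiply to
256 and the products reproduce the enumerated library byte for byte.

**The synthetic region.** The 270-bp fixture region (`hcm1Region()`,
`inst/extdata/hcm1_tad_synthetic.fasta`) is a deterministic synthetic
stand-in, not the real Hcm1 sequence: it embeds the eight S/T-P sites at
the correct relative spacing of the published residue numbers (T428, T440,
T447, T460, S471) inside a fixed filler backbone. The three C-terminal TAD
sites have no published residue numbers; they are labelled S6/S7/S8 at
placeholder positions 482/489/496 used only to anchor the fixture, and the
priming-spacing analysis of those sites is correspondingly not
authoritative.

## Group summaries

Per-count groups pool **replicate-level** SC values of all genotypes with
exactly $k$ sites in a state ($\binom{8}{k}$ genotypes, $3\binom{8}{k}$
values for triplicates); per-site groups pool the half-library
($2^7 = 128$ genotypes) carrying a given state at a given site. Boxplot
statistics follow the Tukey convention (whiskers at the most extreme value
within 1.5 × IQR of the quartiles, points beyond reported as outliers) with
type-7 quantile interpolation — R's `boxplot()` defaults, which is what
screen figures conventionally use; the choice is stated here because other
quantile types would shift quartiles of small groups. `cumulativeSC()`
returns the right-continuous empirical CDF, and `replicateCorrelation()`
the pairwise Pearson correlations of per-replicate SC vectors.

## Accessory computations

* `candidatePrimingPairs()` enumerates candidate Cks1 priming
  relationships: ordered site pairs whose upstream member is a threonine
  (Cks1 binds phosphothreonine, not phosphoserine) with phosphoacceptor
  spacing of 12–30 residues inclusive. Over the five published TAD sites
  this yields exactly {428→440, 428→447, 440→460, 447→460, 447→471};
  460→471 is excluded at spacing 11.
* `betaGalUnits()` implements the standard lacZ reporter normalization
  $1000 \cdot \mathrm{OD}_{405} / (\mathrm{OD}_{600} \cdot V_\mathrm{mL}
  \cdot t_\mathrm{min})$.
* `doublingTime()` fits $\log_2 \mathrm{OD}$ against time restricted to the
  0.2–0.5 OD window (bounds inclusive, absolute OD — deliberately not
  invariant to rescaling the readings) and returns 1/slope; non-positive
  slopes are reported as non-growing.

## Numerical and design choices

* **Genotype encoding** is a plain string in N→C site order (`"AAAEEAAA"` =
  E-E at sites 4 and 5), stable as table keys and file identifiers;
  enumeration is the lexicographic Cartesian product of per-site alphabets.
* **OLS** is closed-form on centered time (verified against `lm()`); all
  timepoints enter one fit per replicate, unweighted — no $t_0$ dropping,
  no error-model weighting (Enrich2-style shrinkage is deliberately out of
  scope).
* **Determinism**: stochastic layers require an explicit seed; each
  replicate gets an independent stream derived from it; `runScreen()`
  re-runs are byte-identical, and the run log records the library hash
  (a digest of the sorted genotype list) to guard against scheme drift
  between counting and fitness stages.
* **Degenerate inputs** fail loudly: empty per-site alphabets, all-zero
  timepoints, a missing reference, 0%/100% pairwise compositions,
  out-of-frame regions, infeasible tilings and window-ambiguous allele
  sets are all errors with named causes.
* **Problem sizes in the checks**: the recovery suite runs the full
  257-member pool at $10^6$ pairs/timepoint and $10^7$-cell bottlenecks
  (seconds of compute, since only multinomial draws scale with depth);
  FASTQ-level round trips use $2\times 10^4$ pairs per sample, ample for
  the $3\sigma$ binomial attrition check at $\varepsilon = 10^{-3}$.

## Known limitations

* Exact-match counting discards all reads carrying any error in either
  window (~26% at PE150 and $\varepsilon = 10^{-3}$); this is unbiased
  across genotypes (tested) but wasteful compared to alignment-based
  callers — it is retained because it is the published convention and has
  zero false-assignment risk under the fixture's distance property.
* Analyses of the real deposited screen data require mapping the deposited
  count tables into the interchange schema (`readCountTable()` has a
  column-rename adapter); the package does not bundle those data.
* The simulator's multinomial layers understate real overdispersion
  (bottleneck-passage jackpots, PCR amplification noise), so real-data SC
  standard deviations will exceed the simulated ones at equal depth.
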