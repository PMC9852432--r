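# PhosphoScan

Design and analysis of **phosphosite scanning** screens: pooled fitness
competitions over combinatorial phosphosite-mutant libraries.

Many kinase substrates — CDK substrates in particular — are phosphorylated
on clusters of S/T-P consensus sites inside disordered regions, and it is
usually unknown which sites, or which combinations, carry regulatory
function. Phosphosite scanning answers this by building every combination
of per-site states — wild type (`W`), unphosphorylatable A-P (`A`),
phosphomimetic E-E (`E`) — over the sites of a domain (2⁸ = 256 mutants for
an eight-site domain), competing the pooled mutants through a
serial-dilution time course, and reading allele frequencies out by
paired-end amplicon sequencing. PhosphoScan covers the computational side
end to end, for people running or reanalyzing such screens:

* **Library design** — phosphosite schemes, genotype enumeration,
  genotype → protein/DNA realization, mutagenic-oligo tile planning with
  overlap constraints, and enumeration of overlap-extension assembly
  products.
* **Counting** — exact-match paired-end assignment of reads to alleles
  (a pair counts only if both mates match the same allele's sequence
  windows with zero mismatches), with conservation-checked discard
  tallies; counts live in a `ScreenCounts` container (a
  `SummarizedExperiment`).
* **Fitness** — per-mutant **selection coefficients**: per replicate, the
  OLS slope of log₂ read fraction versus time (hours) minus the reference
  allele's slope,

  SC<sub>g,r</sub> = slope(log₂ f<sub>g,r</sub>(t)) − slope(log₂ f<sub>ref,r</sub>(t)),

  so SC(reference) ≡ 0, deleterious mutants are negative, beneficial ones
  positive; plus enrichment matrices (log₂ fold change vs t₀, normalized
  to the reference) and pairwise co-culture SCs.
* **Summaries** — median SC by number of substitutions and by per-site
  state (Tukey boxplot statistics), empirical SC CDFs, replicate
  correlations.
* **Simulation** — a pooled serial-dilution competition simulator
  (exponential growth per genotype, multinomial bottleneck and sequencing
  layers, paired FASTQ emission) so the whole pipeline is testable without
  wet-lab data.
* **Accessories** — Cks1 priming-pair enumeration (phosphothreonine
  priming, 12–30 residue spacing), β-galactosidase units, doubling times.

A thin CLI (`exec/phosphoscan`) exposes
`design | simulate | count | fitness | groups | assays | run` over the same
functions; `runScreen()` orchestrates count → fitness → summaries from a
YAML configuration and writes deterministic TSV outputs.

## Worked example

Simulate an A/E screen at the canonical conditions (256 mutants + spiked
wild-type reference, 7 timepoints over 72 h every 12 h, 3 replicates,
10⁷-cell bottleneck, 10⁶ read pairs per timepoint), then estimate and
summarize selection coefficients:

```r
library(PhosphoScan)

spec <- hcm1LibrarySpec("AE")       # 8 sites x {A, E}; reference WWWWWWWW
pool <- poolGenotypes(spec)         # 256 mutants + spiked WT = 257

set.seed(7)
s <- setNames(runif(length(pool), -0.02, 0.02), pool)
s["WWWWWWWW"] <- 0                  # reference defines zero
s["EEEEEEEE"] <- 0.016              # strongly activating mimetic
s["AAAAAAAA"] <- -0.03              # unphosphorylatable, deleterious

cn  <- simulatePool(competitionModel(pool, s = s), 3, noise = TRUE, seed = 7)
fit <- estimateSC(cn, "WWWWWWWW")
fit
#> FitnessTable: 257 genotypes, 3 replicates; reference WWWWWWWW
#>   mean SC range: [ -0.03 , 0.0195 ] log2/h

round(scMean(fit)[c("AAAAAAAA", "AAAEEAAA", "EEEEEEEE", "WWWWWWWW")], 4)
#> AAAAAAAA AAAEEAAA EEEEEEEE WWWWWWWW
#>  -0.0300   0.0193   0.0159   0.0000
```

The recovered mean SCs match the simulated truth (−0.03 and 0.016 for the
all-A and all-E mutants; the reference is exactly 0 by construction).
Group summaries and reproducibility checks:

```r
byK <- groupByCount(fit, "E", genotypes = enumerateLibrary(spec))
head(byK[, c("k", "n_genotypes", "n_values", "median")], 4)
#>   k n_genotypes n_values        median
#> 1 0           1        3 -0.0296650063
#> 2 1           8       24 -0.0070987157
#> 3 2          28       84  0.0050185583
#> 4 3          56      168  0.0003054992

round(replicateCorrelation(fit), 4)
#>        1      2      3
#> 1 1.0000 0.9983 0.9984
#> 2 0.9983 1.0000 0.9979
#> 3 0.9984 0.9979 1.0000
```

Each k-of-8 group holds choose(8, k) genotypes and three replicate values
per genotype; medians are Tukey/type-7 statistics over the pooled
replicate-level SCs. Candidate Cks1 priming pairs over the five
published Hcm1 TAD sites:

```r
sites <- phosphositeScheme(c("T428", "T440", "T447", "T460", "S471"),
                           c(428L, 440L, 447L, 460L, 471L),
                           c("T", "T", "T", "T", "S"), c(415L, 504L))
candidatePrimingPairs(sites)[, c("primer", "target", "spacing")]
#>   primer target spacing
#> 1   T428   T440      12
#> 2   T428   T447      19
#> 3   T440   T460      20
#> 4   T447   T460      13
#> 5   T447   S471      24
```

Only threonines prime (S471 primes nothing) and 460→471 is excluded at
spacing 11 < 12.

Real data enter either as paired FASTQ (via a manifest and
`countScreen()`/`runScreen()`) or as a long-format count TSV
(`genotype, replicate, timepoint_h, count`; `readCountTable()` has a
column-rename adapter for foreign schemas).

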