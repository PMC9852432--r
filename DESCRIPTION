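Package: PhosphoScan
Title: Design and Analysis of Combinatorial Phosphosite-Mutant Fitness Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for phosphosite scanning: design of combinatorial
    phosphosite-mutant libraries over multisite-phosphorylated domains
    (wild-type, unphosphorylatable A-P and phosphomimetic E-E states at each
    CDK consensus site), planning of overlapping mutagenic oligonucleotide
    tiles and enumeration of their overlap-extension assembly products,
    exact-match paired-end counting of mutant alleles from pooled-competition
    amplicon sequencing, estimation of per-mutant selection coefficients from
    log2 read-fraction time courses, and summaries of the phosphorylation
    code (per-site and per-count effects, cumulative distributions, replicate
    correlations). Includes a pooled serial-dilution competition simulator
    with multinomial bottleneck and sequencing layers so the entire pipeline
    can be exercised and validated without experimental data, plus small
    accessory computations (Cks1 priming-site spacing, beta-galactosidase
    units, doubling times).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, graphics, grDevices, Biostrings, IRanges,
    S4Vectors, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
biocViews: Sequencing, SequenceMatching, MultipleComparison, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'PhosphoScan-package.R'
    'assays.R'
    'counting.R'
    'fitness.R'
    'groupstats.R'
    'hcm1.R'
    'scheme.R'
    'oligo.R'
    'run.R'
    'simulate.R'
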