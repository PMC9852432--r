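# Example screen configuration: the built-in synthetic Hcm1 TAD scheme with
# the A/E library.  Point counts_tsv (or fastq_manifest) at your data.
allowed_states: [A, E]
reference_genotype: WWWWWWWW
pseudocount: 0.5
read_length: 150
# counts_tsv: counts.tsv
# fastq_manifest: manifest.tsv
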