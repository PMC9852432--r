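>hcm1_tad_synthetic_region
GATTTGAAATCTGGTCAAAATGAACCAGTTGATTTGAAAACCCCTCAAAATGAACCAGTTGATTTGAAATCTGGTACCCC
TGAACCAGTTGATTTGACCCCTGGTCAAAATGAACCAGTTGATTTGAAATCTGGTACCCCTGAACCAGTTGATTTGAAAT
CTGGTCAATCCCCTCCAGTTGATTTGAAATCTGGTCAAAATTCCCCTGTTGATTTGAAATCTTCCCCTAATGAACCAGTT
GATTCCCCTTCTGGTCAAAATGAACCAGTT
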