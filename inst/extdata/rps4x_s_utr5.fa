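>Rps4x.S_utr5 Xenopus laevis Rps4x.S 5' UTR (transcribed sequence, 72 nt)
cgcgctctcttcctgccagagttcagcgcgcactctttatcccggcgggaccggaaggaggaggtcttttcc
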