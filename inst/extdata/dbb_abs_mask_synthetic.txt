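# 1-based codon indices of the antigen-binding-site partition
4
9
12
16
21
25
28
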