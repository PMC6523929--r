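>DBB1-01_synthetic
ATGGAGTGGGCTAAATTCGTTCGTCACCTGGATTACACTGGATCCAAGGAATTTGTCCGCCATCTCGACTATACAGGTTCTAATGAGTGG
>DBB2-01_synthetic
ATGGAGTGGACTAAATTTGTTCGTCACCTGGATTGCACTGGATCCAAGGAATTTGTCCGCCATCTCGACTATACAGGTTCTAATGAGTGG
>DBB2-02_synthetic
ATGGAGTGGGCTAAATTCGTTCGTCGCCTGGATTACACTGGGTCCAAGGAATTTGTCCGCAATCTCGACTATACAGGTTCTAATGAGTGG
>DBB3-01_synthetic
ATGGAGTGGGCTAAATTCGTTCGTCACTTGGATTACACTGGATCCGAGGAATTTGTCCGCCATCTCGACTATGCAGGTTCTAGTGAGTGG
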