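sequence	weight
DBB1-01_synthetic	2
DBB2-01_synthetic	1
DBB2-02_synthetic	2
DBB3-01_synthetic	1
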