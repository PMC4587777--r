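# golden per-step survivor counts, hand-derived from the fixture plan
step	n_survivors
input	50
frequency	35
zygosity	27
autozygome	20
consequence	14
predictions	8
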