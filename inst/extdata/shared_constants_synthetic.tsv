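constant	value
kAH1	5e2
kAH2	1e2
kAH3	1e1
kt4	1e3
kt5	1e2
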