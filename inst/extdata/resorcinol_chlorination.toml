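# Sequential chlorination of resorcinol: published macroscopic constants
[design]
mode = "chlorination"
e0 = 6
replicates = 2

[parameters.cycle1]
kcat = 2.3
km = 0.076
ka = 100

[parameters.cycle2]
kcat = 0.40
km = 0.11
ka = 100
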