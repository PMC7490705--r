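taxon,germination_pct,survival_pct,fecundity
Saccharum spontaneum,9,47,2000
Typha sp(p).,18,91,250000
Phragmites sp(p).,26,89,9500
Andropogon sp(p).,37,62,100
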