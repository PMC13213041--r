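# Hypothesized cortisol-induced neurotoxicity cascade (editable template).
# Variables are gene symbols; one directed edge per line. The exact node and
# edge set of a cascade is a scientific hypothesis, not package truth: edit
# freely and refit. 6 genes, 11 connections.
HSD11B1 -> NR3C1
HSD11B1 -> H6PD
HSD11B1 -> GNAI2
HSD11B1 -> GRIN2A
H6PD -> GNAI2
H6PD -> GRIN2A
NR3C1 -> GNAI2
NR3C1 -> GRIN2A
NR3C1 -> GRIN2B
GNAI2 -> GRIN2B
GRIN2A -> GRIN2B
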