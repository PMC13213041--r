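# Hypothesized ROS/JNK/p53 apoptosis cascade (editable template).
# Oxidative stress -> JNK -> p53 -> pro-apoptotic effectors -> apoptosis
# initiation. 7 genes, 12 connections.
SOD2 -> MAPK8
SOD2 -> CYCS
MAPK8 -> TP53
MAPK8 -> BCL2L1
MAPK8 -> BAX
TP53 -> PMAIP1
TP53 -> BCL2L1
TP53 -> BAX
TP53 -> CYCS
PMAIP1 -> BCL2L1
BCL2L1 -> BAX
BAX -> CYCS
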