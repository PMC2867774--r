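# Gene expression: transcription, translation, degradation (infinite space)
name gene_expression_a
species M 0
species P 0
reaction 0 -> M @ 0.5
reaction M -> M + P @ 0.0058
reaction M -> 0 @ 0.0029
reaction P -> 0 @ 0.0001
branch max_M MORE AVG FEWER AVG
branch min_M FEWER AVG MORE AVG
branch max_P MORE MORE FEWER FEWER
branch min_P FEWER FEWER MORE MORE
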