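# Enzyme-catalysed substrate conversion, parameter set a
name enzyme_a
species E 1000
species S 100
species ES 0
species P 0
reaction E + S -> ES @ 1
reaction ES -> E + S @ 1
reaction ES -> E + P @ 0.1
branch max_ES/min_E MORE FEWER FEWER
branch min_ES/max_E FEWER MORE MORE
branch min_P/max_S FEWER MORE FEWER
branch max_P/min_S MORE FEWER MORE
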