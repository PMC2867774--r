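# Bistable toggle switch: two mutually repressing proteins, Hill production
name toggle_switch
species A 0
species B 0
reaction 0 -> A ; propensity = 3000 / (11000 + B^2)
reaction A -> 0 @ 0.001
reaction 0 -> B ; propensity = 3000 / (11000 + A^2)
reaction B -> 0 @ 0.001
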