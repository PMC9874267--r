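# High-transmissibility bistable setup: both resistance traits cost
# mortality; hosts evolve either to high resistance at both stages or none.
beta0: 1000
f: 0.5
alpha: 0
juvenile_target: juvenile_mortality
adult_target: adult_mortality
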