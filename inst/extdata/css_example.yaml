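# Benchmark continuously-stable-strategy setup: strong sterility virulence,
# juvenile resistance costing juvenile mortality, adult resistance costing
# reproduction.
beta0: 8
f: 0.1
alpha: 0
juvenile_target: juvenile_mortality
adult_target: reproduction
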