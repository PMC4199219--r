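# CA1 pyramidal-cell single-compartment noise report (approximate built-in
# kinetics; see ?get_scheme).
model: ca1
experiment: noise-report
areas: [1000]
voltage: -65
seed: 1
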