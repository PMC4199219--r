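# Standard squid-axon single-compartment experiment: fully stochastic
# spontaneous-rate sweep over membrane area.
model: hh
experiment: rate-vs-area
areas: [50, 100, 200, 400]
duration: 10000
dt: 0.005
seed: 1
threshold: -20
refractory: 2
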