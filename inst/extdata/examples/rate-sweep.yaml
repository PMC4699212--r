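# 30 x 30 grid over the two update rates; all other parameters as in the
# stochastic-switching example.
delta: 0.6
sigma: 1
beta: 0.5
mode: "stochastic"
K: 6
pi2_init: 0.0001
target_phases: 500
base_seed: 1
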