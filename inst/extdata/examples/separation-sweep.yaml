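# Deterministic separation/width grid plus stochastic build-up curves.
gamma: 0.1
eta_tilde: 0.05
beta: 0.5
pi2_init: 0.001
deltas: [1, 2, 3, 4, 5, 6, 7, 8]
sigmas: [1, 2, 4, 8]
n_elements: 30000
buildup_deltas: [2, 4, 6, 8]
buildup_sigma: 4
n_runs: 100
horizon: 600
K: 6
base_seed: 1
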