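# Long stochastic run with the K-counter switching rule: bistable percept
# with variable phase durations and evidence-duration correlations.
gamma: 0.03
eta: 0.1
sigma: 1
beta: 0.5
delta: 0.6
pattern: "ABA-"
mode: "stochastic"
K: 6
pi2_init: 0.0001
target_phases: 1572
seed: 1
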