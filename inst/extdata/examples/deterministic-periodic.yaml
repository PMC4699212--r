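# Deterministic (argmax) classification: after a transient, the model
# settles into periodic switching between integration and segregation.
gamma: 0.1
eta: 0.5
sigma: 1
beta: 1.5
delta: 5
pattern: "ABA-"
mode: "deterministic"
pi2_init: 0.0001
n_elements: 6000
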