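# Example simulation configuration: DNA-relay model with a slow
# hydrolysis rate; unspecified keys take the package defaults.
model: dna_relay
k_cat: 0.003
n_runs: 25
seed: 7
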