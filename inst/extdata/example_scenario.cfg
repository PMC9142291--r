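# example scenario: baseline rates with a softer relapse rate and a
# shorter fractional sweep; unspecified keys fall back to the baseline
f = 0.15
sigma = 0.9
h = 0.02
t_end = 20
orders = 1.0,0.9,0.8
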