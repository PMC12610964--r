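state,pi
T,0.108
H,0.085
THI,0.083
F,0.088
M,0.147
L,0.209
S,0.085
RS,0.086
RL,0.106
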