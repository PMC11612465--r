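tube,n_frames
A,18
B,10
C,10
D,7
E,10
F,7
G,10
H,7
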