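label,d_high,d_low,rings
A,3.975,3.821,3.895
B,3.742,3.596,3.661
C,3.510,3.372,3.439
D,2.724,2.618,2.668
E,2.294,2.204,2.249
F,2.113,2.031,2.068
G,1.975,1.906,1.948+1.916
H,1.905,1.860,1.882
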