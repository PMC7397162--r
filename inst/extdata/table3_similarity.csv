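item,A,B,C,D
A,1.00,0.14,-0.31,-0.55
B,0.14,1.00,0.44,0.52
C,-0.31,0.435,1.00,0.94
D,-0.55,0.516,0.94,1.00
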