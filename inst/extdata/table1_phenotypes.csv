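line,A,B,C,D
1,NA,2.00,1.50,2.25
2,1.75,NA,2.25,3.00
3,1.50,2.25,NA,2.75
4,2.00,3.00,2.00,NA
5,1.25,2.75,2.00,3.00
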