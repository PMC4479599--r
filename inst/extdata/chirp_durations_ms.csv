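subject,control,A,B,C,D,E,F
Bart,53.7,NA,64.2,54.2,58.7,59.3,NA
Milhouse,60.0,61.1,59.5,58.8,65.7,76.3,64.9
Susan,60.6,76.3,59.9,60.1,67.4,65.0,74.9
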