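call_type,subject,control,treatment
CLC,Bart,23,24
CLC,Jerry,18,30
CLC,Mulva,33,31
chirp,Bart,91,77
chirp,Milhouse,245,185
chirp,Susan,156,79
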