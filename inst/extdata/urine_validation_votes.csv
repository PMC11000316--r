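PatientId,DiagnosedDisease,SoftVoting,HardVoting
121,BPH,0,0
133,BPH,0,0
39,BPH,0,0
68,BPH,0,0
84,BPH,0,0
91,BPH,1,1
1,PCa,1,1
125,PCa,1,1
126,PCa,1,1
141,PCa,0,0
17,PCa,1,1
87,PCa,1,1
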