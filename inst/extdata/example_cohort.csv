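Id,Age,ProstateGlandSize,TotalPsa,FTratio,PsaFree,Disease,sema7a
id100,57,95.00,8.94,24.0,2.14,BPH,15300
id19,73,NaN,0.07,71.0,0.05,BPH,29200
id74,47,20.0,6.97,8.0,0.59,PCA,31800
id306,62,50.0,19.71,10.0,1.97,PCa,9230
id144,73,NaN,1.83,16.0,0.29,PCa,28300
id142,72,NaN,8.05,21.0,1.71,PCa,22800
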