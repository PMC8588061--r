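ref_mgdl,pred_mgdl,zone
100,100,A
50,40,A
150,180,A
150,190,B
165,130,B
160,30,C
100,250,C
250,100,D
50,100,D
200,50,E
50,200,E
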