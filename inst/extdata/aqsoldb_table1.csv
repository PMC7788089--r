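source_id,size,filtered_size,n_sd,sd
A,6110,3266,3093,0.717
B,4651,3185,1215,0.372
C,2603,1798,668,0.380
D,2115,1054,179,0.361
E,1291,1290,337,0.274
F,1210,1011,202,0.582
G,1144,363,170,0.392
H,578,148,100,0.383
I,94,62,46,0.338
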