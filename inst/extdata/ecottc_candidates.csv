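verhaar_class,empirical_ng_L,normal_ng_L,logistic_ng_L
1,5.496,5.587,5.929
2,9.455,37.53,44.45
3,1.254,2.534,2.982
4,0.134,0.1433,0.1175
5,4.012,5.434,5.750
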