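verhaar_class,ecottc_ng_L
1,45
2,19
3,15
4,0.2
5,4
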