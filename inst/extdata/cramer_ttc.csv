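cramer_class,ttc_ug_kgbw_day
1,30
2,9
3,1.5
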