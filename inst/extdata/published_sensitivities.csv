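lld_keV,uld_keV,s_i124_pct,s_f18_pct
350,550,1.57,6.44
350,600,1.78,6.51
350,650,2.04,6.54
350,750,2.26,6.61
400,590,1.31,5.43
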