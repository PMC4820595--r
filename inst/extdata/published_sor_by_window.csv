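lld_keV,uld_keV,sor_air_pct,sor_water_pct,wsor
350,550,-5.03,1.01,1.30
350,600,-4.33,1.26,1.43
350,625,-3.40,1.80,1.86
350,650,-2.68,2.87,2.86
350,675,-4.14,2.15,2.22
350,700,-6.47,0.79,1.32
350,725,-5.85,0.39,1.03
350,750,-5.54,0.26,0.95
350,775,-5.77,1.58,1.83
350,800,-5.41,2.36,2.49
400,590,-5.75,1.40,1.67
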