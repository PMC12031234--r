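excitation_nm,modality,power_mw,exposure_ms,aotf_nm,filter,detected_nm
532,rayleigh,1,100,522,none,532
532,raman,350,400,631.6,longpass 532,631.6
660,rayleigh,1,100,650,none,660
660,raman,130,5000,815,longpass 660,815
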