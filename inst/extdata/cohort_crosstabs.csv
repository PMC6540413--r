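name,cohort,comparison,a,b,c,d,expected_or,digits
fccc_til_high2_4,FCCC,"TIL high (2-4) vs low (0-1) by recurrence",38,89,15,56,1.59,2
fccc_til_high3_4,FCCC,"TIL high (3-4) vs low (0-2) by recurrence",29,50,24,95,2.29,2
uab_necrosis,UAB,"necrosis yes vs no by recurrence",18,30,15,96,3.8,1
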