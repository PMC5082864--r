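"label","L","L_path","V_cap","R0","d","A","R_resistance","N_max_numeric"
"Image 1",185,147,12728,NA,51,5446.8,0.00058,3.2e-06
"Image 2",164,164,19108,NA,15,6508.1,4e-04,6.6e-06
"Image 3",92,80,6477,NA,22,2669.04,3e-04,2.7e-06
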