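group,dose,n_injected,n_positive
virgin_c,1000,9,8
virgin_c,500,11,8
virgin_c,250,6,2
virgin_c,100,6,0
virgin_c,50,7,0
parous_c,1000,9,3
parous_c,500,11,2
parous_c,250,6,0
parous_c,100,6,0
parous_c,50,7,1
virgin_d,1000,9,8
virgin_d,500,11,8
virgin_d,250,6,2
virgin_d,100,6,1
virgin_d,50,7,0
parous_d,1000,9,3
parous_d,500,11,2
parous_d,250,6,1
parous_d,100,6,0
parous_d,50,7,1
parous_e,1000,9,4
parous_e,500,11,6
parous_e,250,6,1
parous_e,100,6,2
parous_e,50,7,1
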