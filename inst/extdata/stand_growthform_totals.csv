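growth_form,density_2002,ba_2002,density_2015,ba_2015,mortality,recruitment,ingrowth
EC,262,20.84,238,22.07,1.344,0.605,1.363
DH,654,10.08,486,11.23,3.370,1.086,2.254
EH,888,4.03,952,4.60,1.613,2.181,2.263
Total,1804,34.95,1676,37.90,2.162,1.614,1.714
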