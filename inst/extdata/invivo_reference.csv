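membrane,drug,cl_invivo_ml_min,sd_ml_min,source
CAHP-210,gentamicin,104.03,12.44,Sowinski 2008
F80s,gentamicin,116,9,Amin 1999
F60s,vancomycin,73.0,5.0,Lanese 1989
F80s,vancomycin,85.2,7.0,Lanese 1989
F60s,teicoplanin,39.70,24.50,Thalhammer 1997
SF21UX,doripenem,148.61,8.41,Vossen 2018
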