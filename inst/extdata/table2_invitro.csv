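membrane,drug,bfr_ml_min,dfr_ml_min,cl_ml_min,cl_uncorrected_ml_min,sd_ml_min,n
CAHP-210,gentamicin,400,800,108.34,NA,24.32,16
F80s,gentamicin,400,800,137.62,NA,12.15,12
F60s,vancomycin,250,500,71.20,NA,4.91,16
F80s,vancomycin,300,500,93.61,NA,31.11,12
F60s,teicoplanin,250,500,38.95,38.95,26.73,16
SF21UX,doripenem,300,500,155.76,NA,18.65,12
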