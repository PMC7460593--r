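label,alpha,se_alpha,beta,se_beta,r_squared
Co60,0.17,3.25e-2,0.03,9.99e-3,0.99
PBS1,0.26,1.13e-3,0.05,2.77e-2,1.00
PBS2,0.20,3.95e-4,0.11,1.27e-2,1.00
DS1,0.13,2.87e-2,0.06,9.49e-3,1.00
DS2,0.12,1.21e-2,0.10,4.99e-3,1.00
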