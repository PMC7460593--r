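position,mode,class,fraction
1,PBS,<=1,0.99999999245
1,PBS,1-50,5.99e-8
1,PBS,>=50,1.56e-8
1,DS,<=1,0.99999999273
1,DS,1-50,6.03e-8
1,DS,>=50,1.24e-8
2,PBS,<=1,0.99999994571
2,PBS,1-50,4.52e-7
2,PBS,>=50,9.09e-8
2,DS,<=1,0.99999994463
2,DS,1-50,4.61e-7
2,DS,>=50,9.27e-8
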