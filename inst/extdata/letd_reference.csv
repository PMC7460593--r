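species,position,mode,letd_kev_um
protons,1,PBS,0.45
protons,1,DS,0.45
protons,2,PBS,3.17
protons,2,DS,3.43
electrons,1,PBS,0.28
electrons,1,DS,0.28
electrons,2,PBS,0.19
electrons,2,DS,0.19
positrons,1,PBS,0.19
positrons,1,DS,0.19
positrons,2,PBS,0.18
positrons,2,DS,0.18
deuterons,1,PBS,5.74
deuterons,1,DS,5.57
deuterons,2,PBS,8.68
deuterons,2,DS,7.40
tritons,1,PBS,7.54
tritons,1,DS,8.27
tritons,2,PBS,8.08
tritons,2,DS,11.16
helions,1,PBS,32.00
helions,1,DS,32.80
helions,2,PBS,59.73
helions,2,DS,42.79
alphas,1,PBS,51.79
alphas,1,DS,51.76
alphas,2,PBS,102.58
alphas,2,DS,103.00
all particles,1,PBS,0.44
all particles,1,DS,0.44
all particles,2,PBS,3.11
all particles,2,DS,3.34
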