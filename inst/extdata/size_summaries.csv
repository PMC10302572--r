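setting,condition,feature,mean,sd
microbej_m200,glutamine,length,1.85,0.44
microbej_m200,alanine,length,2.22,0.59
microbej_m200,glycerol,length,2.61,0.67
microbej_m200,glucose,length,2.73,0.65
microbej_100,glutamine,length,2.16,0.47
microbej_100,alanine,length,2.51,0.67
microbej_100,glycerol,length,2.94,0.72
microbej_100,glucose,length,2.97,0.68
oufti_set1,glutamine,length,2.03,0.47
oufti_set1,alanine,length,2.38,0.56
oufti_set1,glycerol,length,2.77,0.65
oufti_set1,glucose,length,2.81,0.67
oufti_set2,glutamine,length,2.04,0.47
oufti_set2,alanine,length,2.38,0.56
oufti_set2,glycerol,length,2.78,0.64
oufti_set2,glucose,length,2.80,0.66
bacstalk,glutamine,length,2.25,0.48
bacstalk,alanine,length,2.63,0.66
bacstalk,glycerol,length,3.04,0.69
bacstalk,glucose,length,3.11,0.67
custom,glutamine,length,2.11,0.54
custom,alanine,length,2.35,0.45
custom,glycerol,length,2.79,0.88
custom,glucose,length,2.88,0.60
microbej_m200,glutamine,width,0.55,0.06
microbej_m200,alanine,width,0.61,0.06
microbej_m200,glycerol,width,0.67,0.08
microbej_m200,glucose,width,0.79,0.08
microbej_100,glutamine,width,0.75,0.06
microbej_100,alanine,width,0.81,0.06
microbej_100,glycerol,width,0.88,0.08
microbej_100,glucose,width,0.96,0.08
oufti_set1,glutamine,width,0.52,0.03
oufti_set1,alanine,width,0.57,0.02
oufti_set1,glycerol,width,0.60,0.03
oufti_set1,glucose,width,0.72,0.04
oufti_set2,glutamine,width,0.55,0.03
oufti_set2,alanine,width,0.57,0.02
oufti_set2,glycerol,width,0.64,0.03
oufti_set2,glucose,width,0.69,0.03
bacstalk,glutamine,width,0.79,0.06
bacstalk,alanine,width,0.83,0.06
bacstalk,glycerol,width,0.90,0.07
bacstalk,glucose,width,1.00,0.07
custom,glutamine,width,0.55,0.05
custom,alanine,width,0.60,0.05
custom,glycerol,width,0.65,0.05
custom,glucose,width,0.74,0.06
microbej_m200,glutamine,area,0.94,0.26
microbej_m200,alanine,area,1.28,0.36
microbej_m200,glycerol,area,1.66,0.48
microbej_m200,glucose,area,2.03,0.52
microbej_100,glutamine,area,1.51,0.37
microbej_100,alanine,area,1.90,0.54
microbej_100,glycerol,area,2.46,0.66
microbej_100,glucose,area,2.70,0.67
oufti_set1,glutamine,area,1.04,0.25
oufti_set1,alanine,area,1.35,0.33
oufti_set1,glycerol,area,1.64,0.42
oufti_set1,glucose,area,2.00,0.51
oufti_set2,glutamine,area,1.10,0.27
oufti_set2,alanine,area,1.35,0.33
oufti_set2,glycerol,area,1.74,0.43
oufti_set2,glucose,area,1.92,0.49
bacstalk,glutamine,area,1.17,0.26
bacstalk,alanine,area,1.47,0.36
bacstalk,glycerol,area,1.86,0.44
bacstalk,glucose,area,2.13,0.47
custom,glutamine,area,1.02,0.22
custom,alanine,area,1.25,0.24
custom,glycerol,area,1.60,0.30
custom,glucose,area,1.90,0.39
microbej_m200,glutamine,volume,0.39,0.13
microbej_m200,alanine,volume,0.59,0.19
microbej_m200,glycerol,volume,0.85,0.31
microbej_m200,glucose,volume,1.21,0.37
microbej_100,glutamine,volume,0.85,0.24
microbej_100,alanine,volume,1.15,0.37
microbej_100,glycerol,volume,1.62,0.51
microbej_100,glucose,volume,1.92,0.56
oufti_set1,glutamine,volume,0.44,0.11
oufti_set1,alanine,volume,0.63,0.16
oufti_set1,glycerol,volume,0.80,0.22
oufti_set1,glucose,volume,1.18,0.31
oufti_set2,glutamine,volume,0.49,0.13
oufti_set2,alanine,volume,0.63,0.16
oufti_set2,glycerol,volume,0.90,0.23
oufti_set2,glucose,volume,1.09,0.29
bacstalk,glutamine,volume,0.96,0.25
bacstalk,alanine,volume,1.26,0.36
bacstalk,glycerol,volume,1.74,0.48
bacstalk,glucose,volume,2.18,0.57
custom,glutamine,volume,0.46,0.13
custom,alanine,volume,0.59,0.12
custom,glycerol,volume,0.84,0.26
custom,glucose,volume,1.11,0.25
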