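metric,eccentricity_deg,mean,sd
NND,1,3.64,0.39
NND,1.5,4.13,0.35
NND,2,4.62,0.35
NND,4,6.26,0.48
NND,8,8.47,0.39
OS_length,1,30.2,1.6
OS_length,1.5,28.0,1.6
OS_length,2,26.0,2.36
OS_length,4,22.0,3.34
OS_length,8,16.9,3.63
iORG_amplitude,1,36.8,8.71
iORG_amplitude,1.5,33.0,7.53
iORG_amplitude,2,33.9,3.03
iORG_amplitude,4,34.7,7.35
iORG_amplitude,8,28.04,6.75
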