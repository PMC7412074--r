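locus,na,ho,he,pic,fis
SoUZ001,8,0.643,0.661,0.613,0.026
SoUZ002,5,0.643,0.611,0.562,-0.052
SoUZ004,4,0.369,0.367,0.342,-0.005
SoUZ005,7,0.734,0.739,0.694,0.006
SoUZ006,16,0.867,0.836,0.818,-0.037
SoUZ007,11,0.909,0.877,0.864,-0.036
SoUZ011,14,0.830,0.759,0.724,-0.093
SoUZ014,8,0.751,0.757,0.715,0.007
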