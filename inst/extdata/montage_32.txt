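# Recommended 32-channel montage (synthetic stand-in, sensorimotor-centred
# 10-5 subset). One label per line; the reference is marked with '*'.
F3
Fz
F4
FC3
FC1
FCz
FC2
FC4
FCC5h
FCC3h
FCC1h
FCC2h
FCC4h
FCC6h
C5
C3
C1
Cz
C2
C4
C6
CCP5h
CCP3h
CCP1h
CCP2h
CCP4h
CCP6h
CP3
CP1
CP2
CP4
Pz
CPz *
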