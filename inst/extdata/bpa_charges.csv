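atom,charge
N,-0.1804
CA,0.1784
C,0.2422
O,-0.2727
CB,0.0703
CG,-0.0455
CD1,0.0032
CD2,0.0032
CE1,-0.0003
CE2,-0.0003
CZ,-0.0180
B,0.4879
O1,-0.4232
O2,-0.4232
HO1,0.1892
HO2,0.1892
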