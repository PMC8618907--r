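probe,atom,charge
phenylboronic_acid,C1,-0.0180
phenylboronic_acid,C2,-0.0006
phenylboronic_acid,C3,-0.0003
phenylboronic_acid,C4,0.0000
phenylboronic_acid,C5,-0.0003
phenylboronic_acid,C6,-0.0006
phenylboronic_acid,B,0.4879
phenylboronic_acid,O1,-0.4232
phenylboronic_acid,O2,-0.4232
phenylboronic_acid,HO1,0.1892
phenylboronic_acid,HO2,0.1891
p_toluene_boronic_acid,C1,-0.0180
p_toluene_boronic_acid,C2,-0.0004
p_toluene_boronic_acid,C3,0.0028
p_toluene_boronic_acid,C4,-0.0512
p_toluene_boronic_acid,C5,0.0028
p_toluene_boronic_acid,C6,-0.0004
p_toluene_boronic_acid,C7,0.0442
p_toluene_boronic_acid,B,0.4879
p_toluene_boronic_acid,O1,-0.4232
p_toluene_boronic_acid,O2,-0.4232
p_toluene_boronic_acid,HO1,0.1892
p_toluene_boronic_acid,HO2,0.1895
cyclopentylboronic_acid,C1,0.0207
cyclopentylboronic_acid,C2,0.0008
cyclopentylboronic_acid,C3,-0.0003
cyclopentylboronic_acid,C4,-0.0003
cyclopentylboronic_acid,C5,0.0008
cyclopentylboronic_acid,B,0.4542
cyclopentylboronic_acid,O1,-0.4269
cyclopentylboronic_acid,O2,-0.4269
cyclopentylboronic_acid,HO1,0.1888
cyclopentylboronic_acid,HO2,0.1891
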