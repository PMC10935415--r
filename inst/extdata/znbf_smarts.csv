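id,smarts,binding_atoms,denticity,provenance
hydroxamic_acid,[CX3](=[OX1])[NX3][OX2H1],2;4,bidentate,known
sulfonamide,[SX4](=[OX1])(=[OX1])[NX3],4,monodentate,known
urea,[NX3][CX3](=[OX1])[NX3],3,monodentate,known
phosphonate,[PX4](=[OX1])([OX2])[OX2],2,monodentate,known
carboxylic_acid,[CX3](=[OX1])[OX2H1],2;3,bidentate,candidate
thiol,[#6][SX2H1],2,monodentate,candidate
imidazole,c1c[nH]cn1,5,monodentate,candidate
pyridine,[nX2]1ccccc1,1,monodentate,candidate
primary_amide,[CX3](=[OX1])[NX3;!H0],2,monodentate,candidate
hydrazide,[CX3](=[OX1])[NX3][NX3],2,monodentate,candidate
n_hydroxyurea,[NX3][CX3](=[OX1])[NX3][OX2H1],3;5,bidentate,candidate
catechol,[OX2H1]c1ccccc1[OX2H1],1;8,bidentate,candidate
thioamide,[CX3](=[SX1])[NX3],2,monodentate,candidate
phosphonamide,[PX4](=[OX1])[NX3],2,monodentate,candidate
beta_diketone,[CX3](=[OX1])[CX4][CX3](=[OX1]),2;5,bidentate,candidate
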