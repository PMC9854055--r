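name,smiles,formula,logp,source
benzene,c1ccccc1,C6H6,2.13,literature
ethanol,CCO,C2H6O,-0.31,literature
water,O,H2O,-1.38,literature
sodium sulfate,,Na2SO4,0.1,literature
toluene,Cc1ccccc1,C7H8,2.73,literature
hydroquinone,Oc1ccc(O)cc1,C6H4(OH)2,0.59,literature
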