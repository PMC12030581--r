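drug_name,smiles,kind,formula
18-beta-glycyrrhetinic acid,CC1(C)C(O)CCC2(C)C1CCC1(C)C2C(=O)C=C2C3CC(C)(C(=O)O)CCC3(C)CCC12C,small_molecule,C30H46O4
Amikacin,NCCC(O)C(=O)NC1CC(N)C(OC2OC(CN)C(O)C(O)C2O)C(O)C1OC1OC(CO)C(O)C(N)C1O,small_molecule,C22H43N5O13
ASC-J9,COC1=CC=C(/C=C/C(=O)CC(=O)/C=C/C2=CC=C(OC)C(OC)=C2)C=C1OC,small_molecule,C23H24O6
Calcitriol,CC(CCCC(C)(C)O)C1CCC2C1(C)CCCC2=CC=C1CC(O)CC(O)C1=C,small_molecule,C27H44O3
Camptothecin,CCC1(C2=C(COC1=O)C(=O)N3CC4=CC5=CC=CC=C5N=C4C3=C2)O,small_molecule,C20H16N2O4
Carvacrol,CC1=C(O)C=C(C(C)C)C=C1,small_molecule,C10H14O
Cisplatin,N.N.Cl[Pt]Cl,small_molecule,Cl2H6N2Pt
Curcumin,COC1=CC(/C=C/C(=O)CC(=O)/C=C/C2=CC(OC)=C(O)C=C2)=CC=C1O,small_molecule,C21H20O6
Cytarabine,NC1=NC(=O)N(C=C1)C1OC(CO)C(O)C1O,small_molecule,C9H13N3O5
Docetaxel,CC1=C2C(C(=O)C3(C(CC4C(C3C(C(C2(C)C)(CC1OC(=O)C(C(C5=CC=CC=C5)NC(=O)OC(C)(C)C)O)O)OC(=O)C6=CC=CC=C6)(CO4)OC(C)=O)O)C)O,small_molecule,C43H53NO14
Dopamine,NCCC1=CC=C(O)C(O)=C1,small_molecule,C8H11NO2
Emtricitabine,NC1=NC(=O)N(C=C1F)C1CSC(CO)O1,small_molecule,C8H10FN3O3S
Evodiamine,O=C1N2CCC3=C(NC4=CC=CC=C34)C2N(C)C2=CC=CC=C21,small_molecule,C19H17N3O
Felodipine,CCOC(=O)C1=C(C)NC(C)=C(C(=O)OC)C1C1=CC=CC(Cl)=C1Cl,small_molecule,C18H19Cl2NO4
Flavopiridol,CN1CCC(C2=C(O)C=C(O)C3=C2OC(=CC3=O)C2=CC=CC=C2Cl)C(O)C1,small_molecule,C21H20ClNO5
Gemcitabine,NC1=NC(=O)N(C=C1)C1OC(CO)C(O)C1(F)F,small_molecule,C9H11F2N3O4
Ibuprofen,CC(C)CC1=CC=C(C=C1)C(C)C(=O)O,small_molecule,C13H18O2
Lansoprazole,CC1=C(OCC(F)(F)F)C=CN=C1CS(=O)C1=NC2=CC=CC=C2N1,small_molecule,C16H14F3N3O2S
Loperamide,CN(C)C(=O)C(CCN1CCC(O)(C2=CC=C(Cl)C=C2)CC1)(C1=CC=CC=C1)C1=CC=CC=C1,small_molecule,C29H33ClN2O2
Netilmicin,CCNC1CC(N)C(OC2OC(CN)=CCC2N)C(O)C1OC1OCC(C)(O)C(NC)C1O,small_molecule,C21H41N5O7
Paclitaxel,CC1=C2C(C(=O)C3(C(CC4C(C3C(C(C2(C)C)(CC1OC(=O)C(C(C5=CC=CC=C5)NC(=O)C6=CC=CC=C6)O)O)OC(=O)C7=CC=CC=C7)(CO4)OC(C)=O)O)C)OC(C)=O,small_molecule,C47H51NO14
Rhein,O=C(O)C1=CC2=C(C(O)=C1)C(=O)C1=C(C2=O)C(O)=CC=C1,small_molecule,C15H8O6
Rutin,OC1=CC(O)=C2C(=O)C(OC3OC(COC4OC(C)C(O)C(O)C4O)C(O)C(O)C3O)=C(C3=CC=C(O)C(O)=C3)OC2=C1,small_molecule,C27H30O16
Salinomycin,CCC(C(=O)O)C1CCC(C)C(O1)C(C)C(O)C(C)C(=O)C(CC)C2C(C)CC(C)C3(O2)C=CC(O)C4(OC(C)(C5CCC(CC)(O)C(C)O5)CC4)O3,small_molecule,C42H70O11
Sertaconazole,ClC1=CC=C(C(OCC2=CSC3=C2C=CC=C3Cl)CN2C=CN=C2)C(Cl)=C1,small_molecule,C20H15Cl3N2OS
Shikonin,CC(C)=CCC(O)C1=CC(=O)C2=C(O)C=CC(O)=C2C1=O,small_molecule,C16H16O5
Sildenafil,CCCC1=NN(C)C2=C1N=C(NC2=O)C1=CC(S(=O)(=O)N2CCN(C)CC2)=CC=C1OCC,small_molecule,C22H30N6O4S
Tacrolimus,O=C1C2CCCCN2C(=O)C(=O)C2(O)C(C)CC(OC)C(O2)C(OC)CC(C)CC(C)=CC(CC=C)C(=O)CC(O)C(C)C(C(C)=CC2CCC(O)C(OC)C2)O1,small_molecule,C44H69NO12
Temozolomide,CN1N=NC2=C(N=CN2C1=O)C(N)=O,small_molecule,C6H6N6O2
Thienorphine,C7CC7CN1CCC23C4Oc5c(O)ccc(CC1C2(CC6)CC(C(C)(O)CCc8cccs8)C46OC)c35,small_molecule,C31H39NO4S
Insulin,,biologic,
VEGF,,biologic,
Cerebrolysin,,biologic,
DNaseI,,biologic,
Caryota mitis Profilin,,biologic,
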