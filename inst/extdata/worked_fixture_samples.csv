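"sample_id","drug_name","smiles","polymer_mw","pdi","particle_size","zeta_potential","monomer_ratio","encapsulation_efficiency","molecular_weight","logp","hbd_count","hba_count","heavy_atom_count","rotatable_bond_count","tpsa","ring_count","aromatic_ring_count","molar_refractivity","lipinski_mw_ok","lipinski_logp_ok","lipinski_hbd_ok","lipinski_hba_ok","source"
1,"Curcumin","COC1=CC(/C=C/C(=O)CC(=O)/C=C/C2=CC(OC)=C(O)C=C2)=CC=C1O",45,0.18,210,-24.5,0.75,82,,,,,,,,,,,,,,,"synthetic worked fixture"
2,"Ibuprofen","CC(C)CC1=CC=C(C=C1)C(C)C(=O)O",30,0.22,150,-31.2,0.5,68,,,,,,,,,,,,,,,"synthetic worked fixture"
3,"Insulin","",75,,320,,0.5,55,,,,,,,,,,,,,,,"synthetic worked fixture"
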