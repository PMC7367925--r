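compound_id,name,cas,smiles,mw_da,log_kow,k_aw,solubility_mol_l,ppb_fraction_bound,stock_solvent,stock_conc_m,handling_notes
tolbutamide,Tolbutamide,64-77-7,CCCCNC(=O)NS(=O)(=O)c1ccc(C)cc1,270.35,2.34,,0.002,0.95,DMSO,0.1,
paracetamol,Paracetamol,103-90-2,CC(=O)Nc1ccc(O)cc1,151.16,0.46,,0.1,0.15,DMSO,0.1,
colchicine,Colchicine,64-86-8,,399.44,1.3,,0.1,0.40,DMSO,0.1,
sulfisoxazole,Sulfisoxazole,127-69-5,,267.3,1.01,,0.005,0.85,DMSO,0.1,
clofibrate,Clofibrate,637-07-0,,242.7,3.6,,0.002,0.95,DMSO,0.1,
paraquat,Paraquat dichloride,1910-42-5,,257.2,-4.5,,1,0.06,medium,0.1,dissolve freshly in culture medium before each use
mercuric_chloride,Mercuric chloride,7487-94-7,,271.5,0.5,0.02,0.25,0.98,water,0.05,
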