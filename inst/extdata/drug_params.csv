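name,dG_sbd_aqueous_kcal_mol,partition_coefficient,Kd_nbd_M,pc_source
nilotinib,-11.1,25704,2e-9,drugbank
imatinib,-10.3,23988,2e-7,drugbank
dasatinib,-8.8,6606,2.5e-7,drugbank
paclitaxel,-10.9,3467,Inf,drugbank
atp,-7.0,NA,1.16e-5,docking
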