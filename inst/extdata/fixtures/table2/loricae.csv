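lorica_id,tintinnid_taxon,locality,region_class,oral_diameter_um,bowl_length_um,n_loricae,group_label,printed_total_pg
K01,Codonellopsis cf. soyai,Kerguelen Plateau,polar,22.5,,1,,1488
K02,Codonellopsis cf. soyai,Kerguelen Plateau,polar,22.5,,1,,891
K03,Codonellopsis cf. soyai,Kerguelen Plateau,polar,22.5,,1,,1044
K04,Codonellopsis cf. soyai,Kerguelen Plateau,polar,22.5,,1,,475
K05,Codonellopsis cf. soyai,Kerguelen Plateau,polar,22.5,,1,,552
K06,Codonellopsis cf. soyai,Kerguelen Plateau,polar,22.5,,1,,296
K07,Codonellopsis cf. soyai,Kerguelen Plateau,polar,22.5,,1,,180
K08,Codonellopsis cf. soyai,Kerguelen Plateau,polar,22.5,,1,,158
K09,Codonellopsis cf. soyai,Kerguelen Plateau,polar,22.5,,1,,111
K10,Codonellopsis cf. soyai,Kerguelen Plateau,polar,22.5,,1,,25
K11,Codonellopsis cf. soyai,Kerguelen Plateau,polar,22.5,,1,,35
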