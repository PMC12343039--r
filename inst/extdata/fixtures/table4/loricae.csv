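lorica_id,tintinnid_taxon,locality,region_class,oral_diameter_um,bowl_length_um,n_loricae,group_label,printed_total_pg
T01,Codonella galea,Tonga,tropical,51,77,1,,932
T02,Codonella galea,Tonga,tropical,51,77,1,,1058
T03,Codonella galea,Tonga,tropical,51,77,1,,704
T04,Codonella galea,Tonga,tropical,51,77,1,,2869
T05,Codonella galea,Tonga,tropical,51,77,1,,2190
T06,Codonella galea,Tonga,tropical,51,77,1,,1216
T07,Codonella galea,Tonga,tropical,51,77,1,,1366
T08,Codonella galea,Tonga,tropical,51,77,1,,594
T09,Codonella galea,Tonga,tropical,51,77,1,,885
C01,Codonella galea,Coral Sea,tropical,51,77,1,,1472
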