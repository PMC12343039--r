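lorica_id,tintinnid_taxon,locality,region_class,oral_diameter_um,bowl_length_um,n_loricae,group_label,printed_total_pg
D_SOTS,Dictyocysta lepida,Southern Ocean Time Series,temperate,38,,18,SOTS,19922
D_IND,Dictyocysta lepida,Indian Ocean,tropical,38,,5,Indian Ocean,3248
D_TONGA,Dictyocysta lepida,Tonga,tropical,38,,3,Tonga,2428
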