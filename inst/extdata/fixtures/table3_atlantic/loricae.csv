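lorica_id,tintinnid_taxon,locality,region_class,oral_diameter_um,bowl_length_um,n_loricae,group_label,printed_total_pg
NA_CALC,Codonellopsis pusilla,North Atlantic,temperate,20.5,33.5,10,Calcidiscus-dominated,5008
NA_COCC,Codonellopsis pusilla,North Atlantic,temperate,20.5,33.5,5,Coccolithus-dominated,6966
NA_DIAT,Codonellopsis pusilla,North Atlantic,temperate,20.5,33.5,9,F. pseudonana diatom-type,1228
NA_OTH,Codonellopsis pusilla,North Atlantic,temperate,20.5,33.5,11,Others,1276
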