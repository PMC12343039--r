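lorica_id,tintinnid_taxon,locality,region_class,oral_diameter_um,bowl_length_um,n_loricae,group_label,printed_total_pg
SOTS,Codonellopsis pusilla,Southern Ocean Time Series,temperate,18.5,35.5,13,Calcidiscus-ballasted,10540
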