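lorica_id,particle_taxon,particle_kind,quantity_type,quantity
NA_CALC,Emiliania,coccolith,count,104
NA_CALC,Gephyrocapsa,coccolith,count,31
NA_CALC,Calcidiscus,coccolith,count,35
NA_CALC,Coronosphaera,coccolith,count,14
NA_COCC,Emiliania,coccolith,count,81
NA_COCC,Gephyrocapsa,coccolith,count,1
NA_COCC,Helicosphaera,coccolith,count,3
NA_COCC,Coccolithus,coccolith,count,40
NA_DIAT,Emiliania,coccolith,count,187
NA_DIAT,Gephyrocapsa,coccolith,count,19
NA_DIAT,Calcidiscus,coccolith,count,1
NA_DIAT,Coronosphaera,coccolith,count,8
NA_DIAT,Fragilariopsis pseudonana,diatom_cell,mass_pg,34
NA_OTH,Emiliania,coccolith,count,213
NA_OTH,Gephyrocapsa,coccolith,count,146
NA_OTH,Calcidiscus,coccolith,count,13
NA_OTH,Coronosphaera,coccolith,count,16
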