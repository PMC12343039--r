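lorica_id,particle_taxon,particle_kind,x,n
NA_CALC,Fragilariopsis pseudonana,diatom_cell,4,11
NA_COCC,Nitzschia bicapitata,diatom_cell,2,5
ALL,Umbellosphaera,coccolith,1,35
ALL,Helicosphaera,coccolith,1,35
ALL,Coccolithus,coccolith,3,35
ALL,Fragilariopsis pseudonana,diatom_cell,11,35
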