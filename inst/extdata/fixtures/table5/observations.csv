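lorica_id,particle_taxon,particle_kind,quantity_type,quantity
D_SOTS,Calcidiscus,coccolith,count,155
D_IND,Emiliania,coccolith,count,46
D_IND,Umbellosphaera,coccolith,mass_pg,23
D_IND,Helicosphaera,coccolith,count,17
D_TONGA,Emiliania,coccolith,count,74
D_TONGA,Umbellosphaera,coccolith,mass_pg,35
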