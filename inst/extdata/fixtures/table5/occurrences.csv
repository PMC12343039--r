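lorica_id,particle_taxon,particle_kind,x,n
D_SOTS,Emiliania,coccolith,1,18
D_SOTS,Helicosphaera,coccolith,10,18
D_SOTS,Calcidiscus,coccolith,18,18
D_IND,Gephyrocapsa,coccolith,2,5
D_IND,Umbilicosphaera,coccolith,2,5
D_TONGA,Calciosolenia,coccolith,1,3
D_TONGA,Rhabdosphaera,coccolith,1,3
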