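lorica_id,particle_taxon,particle_kind,x,n
SOTS,Gephyrocapsa,coccolith,1,13
SOTS,Coronosphaera,coccolith,1,13
SOTS,Nitzschia bicapitata,diatom_cell,1,13
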