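# Default particle mass reference.
# Per-lith CaCO3 masses (pg) and diatom-particle biovolumes (um^3) are
# literature values; sizes marked "assumed" have no published statement in the
# source compilation and are morphological estimates used only for ordering
# and for the capture simulator, never for mass accounting.
coccoliths:
  Emiliania:
    lith_mass_pg: 4
    size_min_um: 3
    size_max_um: 4
    shape_class: placolith-ellipsoidal
    source: "compiled coccolith weight estimates"
  Gladiolithus:
    lith_mass_pg: 4
    size_min_um: 2
    size_max_um: 3
    shape_class: lath-like
    source: "compiled coccolith weight estimates; size assumed"
  Syracosphaera:
    lith_mass_pg: 10
    size_min_um: 3
    size_max_um: 5.6
    shape_class: placolith-ellipsoidal
    source: "compiled coccolith weight estimates"
  Umbilicosphaera:
    lith_mass_pg: 16
    size_min_um: 4
    size_max_um: 5
    shape_class: placolith-discoidal
    source: "compiled coccolith weight estimates; size assumed"
  Florisphaera:
    lith_mass_pg: 20
    size_min_um: 2
    size_max_um: 3.5
    shape_class: lath-like
    source: "compiled coccolith weight estimates; size assumed"
  Rhabdosphaera:
    lith_mass_pg: 60
    size_min_um: 8
    size_max_um: 12
    shape_class: prolate-rhabdolith
    source: "compiled coccolith weight estimates"
  Calcidiscus:
    lith_mass_pg: 124
    size_min_um: 9
    size_max_um: 9
    shape_class: placolith-discoidal
    source: "compiled coccolith weight estimates"
  Helicosphaera:
    lith_mass_pg: 140
    size_min_um: 6
    size_max_um: 12
    shape_class: placolith-ellipsoidal
    source: "compiled coccolith weight estimates"
  Coccolithus:
    lith_mass_pg: 152
    size_min_um: 6
    size_max_um: 7.8
    shape_class: placolith-discoidal
    source: "compiled coccolith weight estimates"
diatom_particles:
  - {taxon: Pseudo-nitzschia, particle_kind: fragment, biovolume_um3: 25, size_um: 5}
  - {taxon: Chaetoceros, particle_kind: fragment, biovolume_um3: 40, size_um: 10}
  - {taxon: Fragilariopsis, particle_kind: fragment, biovolume_um3: 63, size_um: 6}
  - {taxon: Thalassiothrix, particle_kind: fragment, biovolume_um3: 100, size_um: 15}
  - {taxon: Eucampia, particle_kind: fragment, biovolume_um3: 250, size_um: 10}
  - {taxon: Coscinodiscus, particle_kind: fragment, biovolume_um3: 375, size_um: 12}
  - {taxon: Fragilariopsis pseudonana, particle_kind: whole_cell, biovolume_um3: 100, size_um: 4.5}
  - {taxon: Nitzschia bicapitata, particle_kind: whole_cell, biovolume_um3: 100, size_um: 14}
constants:
  si_pmol_per_um3: 0.0005
  si_pg_per_pmol: 28
  lorica_dry_weight_pg: 40000
  lorica_dry_weight_sd_pg: 20000
aliases:
  # morphological analogy: no published per-lith mass for these taxa
  Gephyrocapsa: Emiliania
  Alisphaera: Emiliania
  Coronosphaera: Syracosphaera
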