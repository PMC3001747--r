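groups:
- meso
- inter
- psychro
assignments:
  fam001_meso_1:
    group: meso
    stratum: orderA
  fam001_meso_2:
    group: meso
    stratum: orderB
  fam001_inter_1:
    group: inter
    stratum: orderA
  fam001_inter_2:
    group: inter
    stratum: orderB
  fam001_psychro_1:
    group: psychro
    stratum: orderA
  fam001_psychro_2:
    group: psychro
    stratum: orderB
  fam002_meso_1:
    group: meso
    stratum: orderA
  fam002_meso_2:
    group: meso
    stratum: orderB
  fam002_inter_1:
    group: inter
    stratum: orderA
  fam002_inter_2:
    group: inter
    stratum: orderB
  fam002_psychro_1:
    group: psychro
    stratum: orderA
  fam002_psychro_2:
    group: psychro
    stratum: orderB
  fam003_meso_1:
    group: meso
    stratum: orderA
  fam003_meso_2:
    group: meso
    stratum: orderB
  fam003_inter_1:
    group: inter
    stratum: orderA
  fam003_inter_2:
    group: inter
    stratum: orderB
  fam003_psychro_1:
    group: psychro
    stratum: orderA
  fam003_psychro_2:
    group: psychro
    stratum: orderB
  fam004_meso_1:
    group: meso
    stratum: orderA
  fam004_meso_2:
    group: meso
    stratum: orderB
  fam004_inter_1:
    group: inter
    stratum: orderA
  fam004_inter_2:
    group: inter
    stratum: orderB
  fam004_psychro_1:
    group: psychro
    stratum: orderA
  fam004_psychro_2:
    group: psychro
    stratum: orderB
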