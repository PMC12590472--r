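pattern_id: abnormalMorphologyOfPartOfAnatomicalEntity
description: >
  Morphology of part of an anatomical entity is abnormal.  Constants are
  the PATO quality 'morphology' (PATO:0000051) and modifier 'abnormal'
  (PATO:0000460); the variable anatomical entity is filled from Uberon.
variables:
  anatomical_entity: UBERON
template:
  genus: PATO:0000051
  modifiers:
    - relation: characteristic_of_part_of
      filler: anatomical_entity
    - relation: has_modifier
      filler: PATO:0000460
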