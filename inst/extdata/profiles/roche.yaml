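# Trial-narrative vocabulary (eCRF-style preferred terms, e.g. pyrexia).
site_id: roche
ici_drugs: [atezolizumab]
labels:
  - label_id: pneumonitis
    display_name: pneumonitis
    synset: []
    category: Pulmonary
  - label_id: colitis
    display_name: colitis
    synset: []
    category: Gastrointestinal
  - label_id: rash
    display_name: rash
    synset: []
    category: Dermatologic
  - label_id: hypothyroidism
    display_name: hypothyroidism
    synset: [hypothyroid]
    category: Endocrine
  - label_id: pyrexia
    display_name: pyrexia
    synset: [fever]
    category: Other
  - label_id: hepatitis
    display_name: hepatitis
    synset: []
    category: Gastrointestinal
  - label_id: wheezing
    display_name: wheezing
    synset: []
    category: Pulmonary
  - label_id: influenza_like_symptoms
    display_name: influenza-like symptoms
    synset: [influenza]
    category: Pulmonary
  - label_id: ards
    display_name: acute respiratory distress syndrome
    synset: [ARDS]
    category: Pulmonary
  - label_id: pleuritis
    display_name: pleuritis
    synset: []
    category: Pulmonary
  - label_id: bladder_tamponade
    display_name: bladder tamponade
    synset: []
    category: Renal
  - label_id: ascending_flaccid_paralysis
    display_name: ascending flaccid paralysis
    synset: []
    category: Neurologic
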