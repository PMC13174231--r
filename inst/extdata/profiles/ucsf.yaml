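# Hospitalisation-cohort vocabulary: colitis and diarrhoea merged under one
# label whose synset carries both surface forms.
site_id: ucsf
ici_drugs: [atezolizumab, ipilimumab, nivolumab, pembrolizumab]
labels:
  - label_id: colitis
    display_name: colitis
    synset: [colitis, diarrhoea]
    category: Gastrointestinal
  - label_id: hepatitis
    display_name: hepatitis
    synset: [transaminitis]
    category: Gastrointestinal
  - label_id: pneumonitis
    display_name: pneumonitis
    synset: []
    category: Pulmonary
  - label_id: rash
    display_name: rash
    synset: [dermatitis]
    category: Dermatologic
  - label_id: fever
    display_name: fever
    synset: []
    category: Other
  - label_id: arthritis
    display_name: arthritis
    synset: []
    category: Musculoskeletal and Rheumatologic
  - label_id: hypophysitis
    display_name: hypophysitis
    synset: []
    category: Endocrine
  - label_id: myocarditis
    display_name: myocarditis
    synset: []
    category: Cardiovascular
  - label_id: stevens_johnson_syndrome
    display_name: Stevens-Johnson syndrome
    synset: [SJS]
    category: Dermatologic
  - label_id: guillain_barre
    display_name: Guillain-Barre syndrome
    synset: [GBS]
    category: Neurologic
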