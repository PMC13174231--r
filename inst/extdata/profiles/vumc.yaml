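# EHR-style site vocabulary: colitis and diarrhoea annotated as separate labels.
# Label lists reconstruct only publicly summarised site vocabularies.
site_id: vumc
ici_drugs: [atezolizumab, avelumab, durvalumab, ipilimumab, nivolumab, pembrolizumab]
labels:
  - label_id: neuropathy
    display_name: neuropathy
    synset: [neurotox, neurotoxicity]
    category: Neurologic
  - label_id: hypothyroid
    display_name: hypothyroid
    synset: [hypothyroidism]
    category: Endocrine
  - label_id: myasthenia_gravis
    display_name: myasthenia gravis
    synset: [MG]
    category: Neurologic
  - label_id: rash
    display_name: rash
    synset: [dermatitis]
    category: Dermatologic
  - label_id: colitis
    display_name: colitis
    synset: []
    category: Gastrointestinal
  - label_id: diarrhoea
    display_name: diarrhoea
    synset: [diarrhea]
    category: Gastrointestinal
  - label_id: adrenal_insufficiency
    display_name: adrenal insufficiency
    synset: [adrenalitis]
    category: Endocrine
  - label_id: hepatitis
    display_name: hepatitis
    synset: [transaminitis]
    category: Gastrointestinal
  - label_id: arthralgia
    display_name: arthralgia
    synset: []
    category: Musculoskeletal and Rheumatologic
  - label_id: duodenitis
    display_name: duodenitis
    synset: []
    category: Gastrointestinal
  - label_id: pancreatitis
    display_name: pancreatitis
    synset: []
    category: Gastrointestinal
  - label_id: hypophysitis
    display_name: hypophysitis
    synset: []
    category: Endocrine
  - label_id: mucositis
    display_name: mucositis
    synset: []
    category: Gastrointestinal
  - label_id: arthritis
    display_name: arthritis
    synset: []
    category: Musculoskeletal and Rheumatologic
  - label_id: pneumonitis
    display_name: pneumonitis
    synset: []
    category: Pulmonary
  - label_id: joint_pain
    display_name: joint pain
    synset: []
    category: Musculoskeletal and Rheumatologic
  - label_id: fever
    display_name: fever
    synset: []
    category: Other
  - label_id: myalgia
    display_name: myalgia
    synset: []
    category: Musculoskeletal and Rheumatologic
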