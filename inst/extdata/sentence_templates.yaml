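# Sentence templates for the synthetic note generator. Placeholders:
#   {term}  - the irAE surface form (display name or a synset term)
#   {ici}   - an ICI drug from the patient's exposures
#   {agent} - a non-ICI etiological agent (alt_cause regime only)
# Templates are data, not code, so assertion regimes can be extended without
# code changes. Positive-causal templates are constructed so the mention is
# positively asserted and causally tied to the ICI; confounder templates place
# their governing cue before the mention (negated/hypothetical) or attach a
# non-ICI agent to the nearest etiology marker (alt_cause).
positive_causal:
  - "{term} attributed to {ici}; corticosteroids initiated."
  - "The patient has developed {term} caused by {ici}."
  - "Assessment: immune-mediated {term} related to {ici} therapy."
  - "New {term}, felt related to {ici}; will start prednisone taper."
negated:
  - "No evidence of {term} on today's evaluation."
  - "Patient denies {term}."
  - "Workup negative for {term}."
  - "Interval imaging and labs without {term}."
hypothetical:
  - "Discussed risk of {term} prior to starting therapy."
  - "Will monitor for {term} during treatment."
  - "Counselled about possible {term} with continued immunotherapy."
alt_cause:
  - "{term} secondary to {agent}."
  - "{term} felt due to {agent} rather than immunotherapy."
  - "{term} in the setting of {agent}; supportive care."
alt_cause_agents:
  - "intercurrent viral infection"
  - "clostridium difficile infection"
  - "recent cytotoxic chemotherapy"
  - "prior radiation therapy"
  - "a course of antibiotics"
distractor:
  - "Routine oncology follow-up visit."
  - "Vital signs reviewed and stable."
  - "Patient tolerating treatment well overall."
  - "Medication list reconciled at this visit."
  - "Follow-up scheduled in three weeks."
  - "Imaging reviewed with the care team."
  - "Labs reviewed; electrolytes within normal limits."
  - "Patient ambulating independently."
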