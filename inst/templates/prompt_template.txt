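You are reviewing a clinical note for a patient who has received immune
checkpoint inhibitor (ICI) therapy. The patient's ICI treatments may include:
{{ici_drugs}}.

Read the patient note below and answer every question about immune-related
adverse events caused by exposure to the patient's ICI treatments.

{{queries}}

{{output_instruction}}

Patient note:
<<<NOTE
{{note_text}}
NOTE>>>
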