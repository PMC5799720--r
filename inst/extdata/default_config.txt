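# Default semantic-type gating configuration.
# 21 prioritized semantic categories (commonly used in the clinical domain)
# and 3 deprioritized ones (too general to have a standalone clinical
# meaning). The full published lists are not public; these defaults encode
# the documented examples plus conventional UMLS clinical categories and are
# meant to be replaced by a user-supplied config where one exists.

[prioritized]
Disease or Syndrome
Pharmacologic Substance
Laboratory or Test Result
Sign or Symptom
Finding
Laboratory Procedure
Diagnostic Procedure
Therapeutic or Preventive Procedure
Body Part, Organ, or Organ Component
Body Location or Region
Neoplastic Process
Pathologic Function
Mental or Behavioral Dysfunction
Injury or Poisoning
Congenital Abnormality
Acquired Abnormality
Anatomical Abnormality
Antibiotic
Clinical Drug
Medical Device
Bacterium

[deprioritized]
Geographic Area
Temporal Concept
Quantitative Concept

[modifiers]
chronic
severe
left
right
acute
mild
moderate
bilateral
upper
lower
anterior
posterior
proximal
distal
recurrent
persistent
diffuse
focal
early
late
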