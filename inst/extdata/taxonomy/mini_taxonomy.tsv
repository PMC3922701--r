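# Mini hypernym/hyponym taxonomy (parent<TAB>child), single root "entity".
# A small offline stand-in for a WordNet-style hierarchy: a drug branch
# (analgesics, diuretics, dissociatives, ...), a clinical-condition branch
# (symptom groups and an injury group), and a non-medical object branch used
# by control text. Synthetic fixture; not extracted from WordNet.
entity	drug
entity	condition
entity	object
drug	analgesic
drug	diuretic
drug	dissociative
drug	stimulant
drug	depressant
drug	cannabis
analgesic	meperidine
analgesic	methadone
diuretic	furosemide
dissociative	ketamine
dissociative	dextromethorphan
stimulant	amphetamine
depressant	ethanol
condition	symptom
condition	injury
symptom	gi_symptom
symptom	neuro_symptom
symptom	cardio_symptom
symptom	psych_symptom
gi_symptom	nausea
gi_symptom	vomiting
gi_symptom	diarrhea
gi_symptom	abdominal_pain
neuro_symptom	dizziness
neuro_symptom	ataxia
neuro_symptom	numbness
neuro_symptom	slurred_speech
neuro_symptom	sensory_change
sensory_change	heaviness
cardio_symptom	tachycardia
psych_symptom	hallucination
psych_symptom	euphoria
psych_symptom	agitation
psych_symptom	psychosis
psych_symptom	depersonalization
psych_symptom	dissociation
injury	bleeding
injury	overdose
object	animal
object	artifact
object	place
animal	penguin
artifact	video
artifact	music
artifact	bottle
place	party
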