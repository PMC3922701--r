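# Clinical symptom lexicon per dose plateau (plateau<TAB>word), paraphrasing
# the established clinical description of dextromethorphan toxicity:
# plateau 1 (100-250 mg) mild stimulant effects; plateau 2 (250-400 mg)
# ethanol/marijuana-like intoxication with occasional hallucinations;
# plateau 3 (450-800 mg) dissociative "out-of-body" state like low-dose
# ketamine; plateau 4 (>800 mg) full dissociation like ketamine
# intoxication, with death reported at the highest doses.
1	stimulant
1	euphoria
1	agitation
1	tachycardia
2	ethanol
2	cannabis
2	hallucination
2	dizziness
2	ataxia
3	dissociation
3	depersonalization
3	ketamine
3	slurred_speech
3	numbness
4	dissociation
4	ketamine
4	psychosis
4	vomiting
4	overdose
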