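# Medical seed nodes: a word counts as medically related when one of its
# concept nodes reaches one of these nodes within the configured number of
# hypernym hops.
symptom
injury
drug
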