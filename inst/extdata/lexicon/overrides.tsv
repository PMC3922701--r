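# Manual Yes/Maybe/No overrides (word<TAB>category). Consulted before the
# taxonomy rule; ships empty of substantive entries apart from examples a
# curator flagged by hand.
satan	No
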