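# Regulation-focused keywords used to select PFAM profiles by description.
# This default list carries only the published example keywords and is
# deliberately incomplete; replace it with a full curated list for real runs.
helix–turn–helix (HTH)
helix–loop–helix (HLH)
repressor
activator
DNA binding
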