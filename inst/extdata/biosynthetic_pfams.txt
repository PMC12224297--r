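# Biosynthesis-associated PFAM domain names counted when scoring candidate
# windows. Editable stand-in list of hallmark secondary-metabolism domains
# (condensation, ketosynthase, adenylate ligase, methyltransferase, P450,
# aminotransferase); extend to match a curated set.
Condensation
ketoacyl-synt
AMP-binding
Methyltransf_12
p450
Aminotran_1_2
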