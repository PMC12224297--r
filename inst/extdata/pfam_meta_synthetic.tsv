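accession	name	ga	description
PF00486	Trans_reg_C	22.4	Transcriptional regulatory protein, C terminal; effector domain with DNA binding winged helix
PF03704	BTAD	24.1	Bacterial transcriptional activator domain
PF00931	NB-ARC	21.9	NB-ARC nucleotide-binding adaptor domain
PF13374	TPR_10	23.0	Tetratricopeptide repeat
PF13424	TPR_12	25.3	Tetratricopeptide repeat
PF13191	AAA_16	24.8	AAA ATPase domain
PF13401	AAA_22	22.7	AAA domain
PF00196	GerE	20.6	Bacterial regulatory proteins, luxR family; DNA binding helix-turn-helix
PF00989	PAS	21.2	PAS fold sensor domain
PF00440	TetR_N	21.1	Bacterial regulatory proteins, tetR family; helix-turn-helix repressor
PF13305	TetR_C_33	23.6	Tetracyclin repressor-like, C-terminal domain of a repressor
PF02518	HATPase_c	20.9	Histidine kinase-, DNA gyrase B-, and HSP90-like ATPase
PF00072	Response_reg	21.5	Response regulator receiver domain; transcriptional activator module
PF01381	HTH_3	20.3	Helix-turn-helix; XRE-family DNA binding domain
PF03477	ATP-cone	22.0	ATP cone domain of the NrdR transcriptional repressor
PF00717	Peptidase_S24	21.7	Peptidase S24 LexA-like; SOS-response transcriptional repressor
PF00376	MerR	20.2	MerR family regulatory protein; DNA binding activator
PF03472	Autoind_bind	23.2	Autoinducer binding domain; quorum-sensing transcriptional activator
PF00668	Condensation	23.9	Condensation domain of nonribosomal peptide synthetases
PF00109	ketoacyl-synt	22.8	Beta-ketoacyl synthase, N-terminal domain
PF00501	AMP-binding	24.3	AMP-binding enzyme, adenylate-forming ligase
PF08242	Methyltransf_12	21.4	Methyltransferase domain
PF00067	p450	23.1	Cytochrome P450 oxidoreductase
PF00155	Aminotran_1_2	22.1	Aminotransferase class I and II
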