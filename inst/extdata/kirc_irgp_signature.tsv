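gene_a	immune_process_a	gene_b	immune_process_b	coefficient
PSMD11	Antigen_Processing_and_Presentation	NFKB1	Antimicrobials/BCRSignalingPathway/TCRsignalingPathway	0.0114928716374979
PSMD11	Antigen_Processing_and_Presentation	F2RL1	Antimicrobials	0.150699162881823
SLC10A2	Antigen_Processing_and_Presentation	AGER	Antimicrobials	-0.0350143079368729
CXCL2	Antimicrobials/Chemokines/Cytokines	GMFB	Cytokines	0.010646975575061
IL6	Antimicrobials/Chemokines/Cytokines	TGFB2	Cytokines/TGFb_Family_Member	0.0131725045908718
TLR7	Antimicrobials	IL20RB	Cytokine_Receptors/Interleukins_Receptor	-0.132192547462545
TYK2	Antimicrobials	KL	Cytokines	0.0225301659700258
IRF9	Antimicrobials	AR	Cytokine_Receptors	0.123358847050174
BIRC5	Antimicrobials	AR	Cytokine_Receptors	0.0167267736278587
PTK2	Antimicrobials	PLCG1	NaturalKiller_Cell_Cytotoxicity/TCRsignalingPathway	-0.0485464799522758
PLAUR	Chemokine_Receptors/Cytokine_Receptors	TEK	Cytokine_Receptors	0.154162736753599
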