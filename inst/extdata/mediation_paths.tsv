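exposure	mediator	outcome	a	b	c
fucose_degradation_pathway_FUCCAT.PWY	CD4_on_CM_CD4pos_Tcell_maturation	PHN	0.239	-0.272	-0.966
Roseburia_inulinivorans	CD28pos_DN_CD4neg_CD8neg_AC_Treg	PHN	0.387	-0.441	-1.356
acetyl_CoA_biosynthesis_superpathway_PWY.5173	CD45_on_lymphocyte_myeloid	TN	0.249	0.135	0.283
GDP_mannose_O_antigen_superpathway_PWY.7323	HLA_DRpos_CD8br_pct_Tcell_TBNK	TN	0.217	-0.056	-0.366
thiazole_biosynthesis_I_pathway_PWY.6892	IgDneg_CD38neg_AC_Bcell	PDPN	0.226	-0.252	-0.759
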