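protein_id	description	lfc_ev_3m	p_ev_3m	lfc_ev_6m	p_ev_6m	lfc_hpc_3m	p_hpc_3m	lfc_hpc_6m	p_hpc_6m	lfc_ctx_3m	p_ctx_3m	lfc_ctx_6m	p_ctx_6m	clinical_trial
Itga2b	Integrin alpha-IIb	-1.3	0.0001	0.6	0.0253	-0.6	0.6532	-2.6	0.1829	-1.0	0.6799	0.2	0.9273	X
Tln1	Talin-1	-1.3	0.0000	0.6	0.0108	0.7	0.1953	1.0	0.0296	0.2	0.6959	0.2	0.7239	X
Flna	Filamin-A	-2.0	0.0000	0.5	0.0174	NA	NA	0.7	0.2041	-3.0	0.0191	3.4	0.0062	X
Itga6	Integrin alpha-6	-2.7	0.0005	1.1	0.0304	NA	NA	NA	NA	NA	NA	NA	NA	X
Tgm2	Protein-glutamine gamma-glutamyltransferase 2	-3.8	0.0000	4.3	0.0042	-0.6	0.6532	0.5	0.5584	0.0	0.9960	0.2	0.8745	X
Mup2	Major urinary protein 2	6.3	0.0000	4.0	0.0109	NA	NA	NA	NA	NA	NA	NA	NA	X
Orm2	Alpha-1-acid glycoprotein 2	4.3	0.0029	2.8	0.0335	NA	NA	NA	NA	NA	NA	NA	NA	X
Mug2	Murinoglobulin-2	NA	NA	6.7	0.0000	NA	NA	NA	NA	NA	NA	NA	NA	X
Flnc	Filamin C	NA	NA	4.6	0.0010	-1.0	0.6823	NA	NA	NA	NA	NA	NA	X
Pfkm	ATP-dependent 6-phosphofructokinase, muscle type	NA	NA	4.6	0.0010	0.0	0.8533	0.1	0.6199	0.0	0.7990	0.0	0.9104	X
Cryaa	Isoform 2 of alpha-crystallin A chain	NA	NA	4.4	0.0026	NA	NA	NA	NA	NA	NA	NA	NA	X
Hspa1l	Heat shock 70-kDa protein 1-like	NA	NA	4.0	0.0109	0.0	0.9405	0.2	0.3304	0.0	0.9587	-0.1	0.7915	X
Vdac1	Voltage-dependent anion-selective channel protein 1	NA	NA	4.0	0.0109	0.1	0.4452	-0.1	0.5607	0.0	0.8182	-0.2	0.1824	X
Ckm	Creatine kinase M-type	NA	NA	3.8	0.0177	-0.1	0.8240	0.4	0.5060	0.0	0.9887	0.2	0.8232	X
A2m	Alpha-2-macroglobulin-P	5.0	0.0001	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	X
Qsox1	Isoform 3 of sulfhydryl oxidase 1	4.3	0.0029	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	X
Hp	Haptoglobin	7.1	0.0000	NA	NA	1.0	0.6839	-2.6	0.0596	1.0	0.6863	-3.1	0.0765	O
H2-L	H-2 class I histocompatibility antigen, L-D alpha chain	4.3	0.0029	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	X
Pltp	Phospholipid transfer protein	3.5	0.0036	NA	NA	NA	NA	-1.0	0.6852	NA	NA	NA	NA	X
Man2b1	Lysosomal alpha-mannosidase	3.3	0.0057	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	X
Pf4	Platelet factor 4	2.4	0.0000	-3.2	0.0000	NA	NA	NA	NA	NA	NA	NA	NA	X
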