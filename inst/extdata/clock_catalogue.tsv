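family	species	gene_name	identifier	relation_to_arabidopsis	partial	core_clock	source
LHY	arabidopsis	AtLHY	At1g01060	reference	FALSE	TRUE	table1
LHY	arabidopsis	AtCCA1	At2g46830	paralogue	FALSE	TRUE	table1
LHY	barley	HvLHY	MLOC_14118	one_to_one_orthologue	FALSE	TRUE	table1
LUX	arabidopsis	AtLUX	At3g46640	reference	FALSE	TRUE	table1
LUX	arabidopsis	AtBOA	At5g59570	paralogue	FALSE	TRUE	table1
LUX	barley	HvLUX	MLOC_37446	one_to_one_orthologue	FALSE	TRUE	table1
ELF3	arabidopsis	AtELF3	At2g25930	reference	FALSE	TRUE	table1
ELF3	barley	HvELF3	MLOC_78552	one_to_one_orthologue	TRUE	TRUE	table1
GI	arabidopsis	AtGI	At1g22770	reference	FALSE	TRUE	table1
GI	barley	HvGI	MLOC_70638	one_to_one_orthologue	TRUE	TRUE	table1
TOC1	arabidopsis	AtTOC1	At5g61380	reference	FALSE	TRUE	table1
TOC1	barley	HvTOC1	MLOC_52387	one_to_one_orthologue	FALSE	TRUE	table1
PRR95	arabidopsis	AtPRR9	At2g46790	reference	FALSE	TRUE	table1
PRR95	arabidopsis	AtPRR5	At5g24470	reference	FALSE	TRUE	table1
PRR95	barley	HvPRR95	MLOC_57021	orthologue_ambiguous	FALSE	TRUE	table1
PRR95	barley	HvPRR59	MLOC_62596	orthologue_ambiguous	TRUE	TRUE	table1
PRR37	arabidopsis	AtPRR7	At5g02810	reference	FALSE	TRUE	table1
PRR37	arabidopsis	AtPRR3	At5g60100	paralogue	FALSE	TRUE	table1
PRR37	barley	HvPpd-H1	MLOC_81154	orthologue_ambiguous	FALSE	TRUE	table1
PRR37	barley	HvPRR73	MLOC_12732	orthologue_ambiguous	FALSE	TRUE	table1
ZTL	arabidopsis	AtZTL	At5g57360	reference	FALSE	TRUE	table1
ZTL	arabidopsis	AtLPK2	At2g18915	paralogue	FALSE	TRUE	table1
ZTL	barley	HvZTLa	MLOC_44010	orthologue_ambiguous	FALSE	TRUE	table1
ZTL	barley	HvZTLb	MLOC_20007	orthologue_ambiguous	FALSE	TRUE	table1
FKF1	arabidopsis	AtFKF1	At1g68050	reference	FALSE	TRUE	table1
FKF1	barley	HvFKF1	MLOC_53725	one_to_one_orthologue	FALSE	TRUE	table1
GRP7	arabidopsis	AtGRP7	At2g21660	reference	FALSE	FALSE	table1
GRP7	arabidopsis	AtGRP8	At4g39260	paralogue	FALSE	FALSE	table1
GRP7	barley	HvGRP7a	MLOC_17819	orthologue_ambiguous	TRUE	FALSE	table1
GRP7	barley	HvGRP7b	MLOC_59695	orthologue_ambiguous	TRUE	FALSE	table1
CO	arabidopsis	AtCO	At5g15840	reference	FALSE	FALSE	table1
CO	arabidopsis	AtCOL1	At5g15850	paralogue	FALSE	FALSE	table1
CO	arabidopsis	AtCOL2	At3g02380	paralogue	FALSE	FALSE	table1
CO	barley	HvCO1	MLOC_6921	orthologue_ambiguous	TRUE	FALSE	table1
CO	barley	HvCO2	MLOC_75496	orthologue_ambiguous	TRUE	FALSE	table1
FT	arabidopsis	AtFT	At1g65480	reference	FALSE	FALSE	table1
FT	arabidopsis	AtTSF	At4g20370	paralogue	FALSE	FALSE	table1
FT	barley	HvFT1	MLOC_68576	orthologue_ambiguous	FALSE	FALSE	table1
FT	barley	HvFT2	MLOC_10172	orthologue_ambiguous	TRUE	FALSE	table1
ELF4	arabidopsis	AtELF4	At2g40080	reference	FALSE	FALSE	table1
ELF4	arabidopsis	AtELF4-like1	At2g29950	paralogue	FALSE	FALSE	table1
ELF4	barley			absent	FALSE	FALSE	table1
ELF4L3	arabidopsis	AtELF4-like3	At2g06255	reference	FALSE	TRUE	table1
ELF4L3	arabidopsis	AtELF4-like2	At1g72630	paralogue	FALSE	TRUE	table1
ELF4L3	arabidopsis	AtELF4-like4	At1g17455	paralogue	FALSE	TRUE	table1
ELF4L3	barley	HvELF4-like3	MLOC_70937	orthologue_ambiguous	FALSE	TRUE	table1
ELF4L3	barley	HvELF4-likeA	MLOC_58590	paralogue	FALSE	TRUE	table1
CHE	arabidopsis	AtCHE	At5g08330	reference	FALSE	FALSE	text
CHE	barley			absent	FALSE	FALSE	text
CAB	arabidopsis	AtCAB2	At1g29920	reference	FALSE	FALSE	text
CAB	barley	HvCABa		paralogue	FALSE	FALSE	text
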