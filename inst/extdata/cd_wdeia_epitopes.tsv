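name	core_native	core_deamidated	disease	source_family	verified
DQ2.5-glia-alpha1a	PFPQPQLPY	PFPQPELPY	CD	alpha	TRUE
DQ2.5-glia-alpha1b	PYPQPQLPY	PYPQPELPY	CD	alpha	FALSE
DQ2.5-glia-alpha2	PQPQLPYPQ	PQPELPYPQ	CD	alpha	TRUE
DQ2.5-glia-alpha3	FRPQQPYPQ	FRPEQPYPE	CD	alpha	FALSE
DQ8-glia-alpha1	QGSFQPSQQ	EGSFQPSQE	CD	alpha	FALSE
DQ2.5-glia-gamma1	PQQSFPQQQ	PQQSFPEQQ	CD	gamma	FALSE
DQ2.5-glia-gamma2	IQPQQPAQL	IQPEQPAQL	CD	gamma	FALSE
DQ2.5-glia-gamma3	QQPQQPYPQ	QQPEQPYPQ	CD	gamma	FALSE
DQ2.5-glia-gamma4a	SQPQQQFPQ	SQPEQEFPQ	CD	gamma	FALSE
DQ2.5-glia-gamma4b	PQPQQQFPQ	PQPEQEFPQ	CD	gamma	FALSE
DQ2.5-glia-gamma4c	QQPQQPFPQ	QQPEQPFPQ	CD	gamma	FALSE
DQ2.5-glia-gamma4d	PQPQQPFPQ	PQPEQPFPQ	CD	gamma	FALSE
DQ2.5-glia-gamma5	QQPFPQQPQ	QQPFPEQPQ	CD	gamma	FALSE
DQ2.5-glia-omega1	PFPQPQQPF	PFPQPEQPF	CD	omega	FALSE
DQ2.5-glia-omega2	PQPQQPFPW	PQPEQPFPW	CD	omega	FALSE
WD-1	QQIPQQQ	-	WDEIA	omega	TRUE
WD-2	QQFPQQQ	-	WDEIA	omega	TRUE
WD-3	QQSPQQQ	-	WDEIA	omega	FALSE
WD-4	QQYPQQQ	-	WDEIA	omega	FALSE
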