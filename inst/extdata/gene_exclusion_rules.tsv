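# Annotation-based gene exclusion rules, one regular expression per line.
# field: which annotation column the (case-insensitive, PCRE) pattern is
# matched against; any match removes the gene. Edit freely.
field	pattern	note
symbol	^OTTHUMG	placeholder Vega-style symbol, no assigned gene symbol
symbol	^SNOR[AD]\d	small nucleolar RNA
description	small nucleolar RNA	small nucleolar RNA
symbol	^SCARNA\d	small Cajal body-specific RNA
description	small Cajal body-specific RNA	small Cajal body-specific RNA
symbol	^RNU\d	small nuclear RNA
description	small nuclear RNA	small nuclear RNA
description	small NF90.associated RNA	small NF90-associated RNA
description	RNA, 5S ribosomal	5S rRNA genes and pseudogenes
symbol	^RNA5S	5S rRNA genes and pseudogenes
description	RNA, 5\.8S ribosomal pseudogene	5.8S rRNA pseudogene
symbol	^RNA5-8S	5.8S rRNA pseudogene
description	^Y RNA	Y RNA
symbol	^MT-RNR	mitochondrially encoded ribosomal RNA
description	mitochondrially encoded (12S|16S) (ribosomal )?RNA	mitochondrial rRNA
symbol	^MIR\d	microRNA
description	^microRNA	microRNA
symbol	^OR\d+[A-Z]	olfactory receptor
description	olfactory receptor(,| family)	olfactory receptor
symbol	^HIST\d	histone cluster gene
description	histone cluster	histone cluster gene
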