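gene_id	chrom	start	stop	annotation
Glyma.14g204500	Chr14	47796602	47808011	NB-ARC domain
Glyma.14g204600	Chr14	47810987	47824929	NB-ARC domain
Glyma.14g204700	Chr14	47831269	47846928	NB-ARC domain
Glyma.14g204800	Chr14	47834239	47834920	No annotation
Glyma.14g205000	Chr14	47855678	47868591	NB-ARC domain
Glyma.14g205100	Chr14	47870805	47877043	KIP1-like protein
Glyma.14g205200	Chr14	47892074	47896155	Cytochrome P450
Glyma.14g205300	Chr14	47895257	47907012	NB-ARC domain
Glyma.14g205400	Chr14	47909453	47911194	No annotation
Glyma.14g205500	Chr14	47911849	47919011	Domain found in IF2B/IF5
Glyma.14g205600	Chr14	47929529	47931437	AP2 domain
Glyma.14g205700	Chr14	47936205	47940755	Ubiquitin-conjugating enzyme
Glyma.14g205801	Chr14	47939508	47939654	No annotation
Glyma.14g206000	Chr14	47946254	47952120	Protein kinase domain
Glyma.14g206100	Chr14	47972022	47975414	BTB/POZ domain/NPH3 family
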