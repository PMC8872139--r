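gene_id	chrom	pos	ref	alt	type	aa_change	aa_change_normalized
Glyma.11g229000	Chr11	37318335	C	T	Synonymous	/	/
Glyma.11g229400	Chr11	37354075	A	G	Nonsynonymous	Glu->Gly	Glu->Gly
Glyma.11g230000	Chr11	37411111	G	C	Nonsynonymous	Gly->Ala	Gly->Ala
Glyma.11g230000	Chr11	37411209	G	C	Nonsynonymous	Val->Leu	Val->Leu
Glyma.11g230200	Chr11	37430249	G	C	Nonsynonymous	Gly->Ala	Gly->Ala
Glyma.11g230200	Chr11	37431363	A	T	Nonsynonymous	Gln->His	Gln->His
Glyma.11g230300	Chr11	37433861	G	C	Nonsynonymous	Val->Leu	Val->Leu
Glyma.11g230300	Chr11	37433873	T	C	Nonsynonymous	Tyr->His	Tyr->His
Glyma.11g230300	Chr11	37435019	G	C	Nonsynonymous	Ala->Pro	Ala->Pro
Glyma.11g230600	Chr11	37469232	T	C	Nonsynonymous	Val->Aal	Val->Ala
Glyma.11g230600	Chr11	37469248	T	C	Synonymous	/	/
Glyma.11g230600	Chr11	37470305	A	C	Nonsynonymous	Thr->Pro	Thr->Pro
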