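gene_id	chrom	start	stop	annotation
Glyma.11g228900	Chr11	37308090	37313815	Cytochrome P450
Glyma.11g229000	Chr11	37315051	37320857	Nuclear pore component
Glyma.11g229100	Chr11	37328504	37331716	Cholesterol-capturing domain
Glyma.11g229300	Chr11	37343716	37352599	ABC1 family
Glyma.11g229400	Chr11	37352888	37356662	Sodium/hydrogen exchanger family
Glyma.11g229500	Chr11	37376823	37382293	GDSL-like lipase/acylhydrolase
Glyma.11g229600	Chr11	37385109	37391331	GINS complex protein
Glyma.11g229700	Chr11	37394752	37395822	Protein of unknown function (DUF1313)
Glyma.11g229800	Chr11	37396251	37399628	Cyclophilin type peptidyl-prolyl cis-trans isomerase/CLD
Glyma.11g229900	Chr11	37404283	37408842	Phosphatidylinositol-specific phospholipase C, X domain
Glyma.11g230000	Chr11	37410777	37417244	Phosphatidylinositol-specific phospholipase C, X domain
Glyma.11g230100	Chr11	37419547	37424310	Phosphatidylinositol-specific phospholipase C, X domain
Glyma.11g230200	Chr11	37425247	37433034	NF-X1-type zinc finger
Glyma.11g230300	Chr11	37433772	37435676	Protein kinase domain
Glyma.11g230400	Chr11	37443779	37446784	Protein kinase domain
Glyma.11g230500	Chr11	37461012	37462619	Protein kinase domain
Glyma.11g230550	Chr11	37464702	37464827	Protein kinase domain
Glyma.11g230600	Chr11	37468983	37471869	Protein kinase domain
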