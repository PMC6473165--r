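family	species	n	k
Alcidae	Atlantic puffin (Witless Bay)	9	2
Alcidae	Atlantic puffin (Gannet Islands)	42	3
Alcidae	Atlantic puffin (total)	51	5
Alcidae	Common murre	41	0
Alcidae	Thick-billed murre	2	0
Alcidae	Razorbill	30	0
Laridae	American herring gull	94	16
Laridae	Great black-backed gull	38	1
Laridae	Iceland gull	4	0
Laridae	Ring-billed gull	9	0
Laridae	Black-legged kittiwake	16	13
Anatidae	Mallard	10	1
Anatidae	American black duck	102	30
Anatidae	American black duck x mallard	4	1
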