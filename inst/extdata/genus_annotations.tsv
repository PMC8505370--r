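genus	trophic	cp	verified
Acrobeles	BF	2	FALSE
Acrobeloides	BF	2	FALSE
Alaimus	BF	4	FALSE
Anaplectus	BF	2	FALSE
Aphelenchoides	FF	2	FALSE
Aphelenchus	FF	2	TRUE
Aporcelaimellus	Om	5	TRUE
Axonchium	Om	5	FALSE
Bastiania	BF	3	FALSE
Boleodorus	PF	2	FALSE
Cephalobus	BF	2	FALSE
Chiloplacus	BF	2	FALSE
Clarkus	Pr	4	TRUE
Criconema	PF	3	FALSE
Diphtherophora	FF	3	FALSE
Eucephalobus	BF	2	TRUE
Eudorylaimus	Om	4	FALSE
Filenchus	FF	2	TRUE
Helicotylenchus	PF	3	TRUE
Hemicycliophora	PF	3	FALSE
Heterocephalobus	BF	2	FALSE
Heterodera	PF	3	FALSE
Lelenchus	PF	2	TRUE
Longidorus	PF	5	FALSE
Malenchus	PF	2	FALSE
Meloidogyne	PF	3	FALSE
Mesodorylaimus	Om	4	FALSE
Mesorhabditis	BF	1	FALSE
Miconchus	Pr	4	TRUE
Microdorylaimus	Om	4	FALSE
Mononchus	Pr	4	FALSE
Panagrolaimus	BF	1	FALSE
Paratrichodorus	PF	4	FALSE
Paratylenchus	PF	2	FALSE
Plectus	BF	2	TRUE
Pratylenchus	PF	3	FALSE
Prismatolaimus	BF	3	FALSE
Prodesmodora	BF	3	TRUE
Prodorylaimus	Om	5	TRUE
Protorhabditis	BF	1	TRUE
Psilenchus	PF	2	FALSE
Rhabditis	BF	1	FALSE
Rotylenchus	PF	3	FALSE
Teratocephalus	BF	3	FALSE
Thonus	Om	4	FALSE
Trichodorus	PF	4	FALSE
Tylencholaimus	FF	4	FALSE
Tylenchorhynchus	PF	3	FALSE
Tylenchus	PF	2	FALSE
Wilsonema	BF	2	TRUE
Xiphinema	PF	5	FALSE
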