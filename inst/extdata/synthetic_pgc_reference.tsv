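symbol	class	ref_index
crtA	crt	1
crtI	crt	2
crtB	crt	3
tspO	other_conserved	4
crtC	crt	5
crtD	crt	6
crtE	crt	7
crtF	crt	8
bchC	bch	9
bchX	bch	10
bchY	bch	11
bchZ	bch	12
pufB	puf	13
pufA	puf	14
pufL	puf	15
pufM	puf	16
pufC	puf	17
bchP	bch	18
pucC	other_conserved	19
bchG	bch	20
ppsR	other_conserved	21
ppaA	other_conserved	22
bchF	bch	23
bchN	bch	24
bchB	bch	25
bchH	bch	26
bchL	bch	27
bchM	bch	28
lhaA	other_conserved	29
puhA	other_conserved	30
puhB	other_conserved	31
puhC	other_conserved	32
acsF	other_conserved	33
puhE	other_conserved	34
cycA	cycA	35
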