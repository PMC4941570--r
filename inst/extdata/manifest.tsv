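class	id	sequence
plate	P1	CATCTTTCG
plate	P2	TGCCACATA
plate	P3	AGTGCAAGC
plate	P4	TCAATCTAC
plate	P5	TCATATCGC
row	A	ATCCCCAC
row	B	ACCACGAG
row	C	GACCGTAG
row	D	TTTCCTTG
row	E	TTCCGAAA
row	F	TAACGACT
row	G	CGCATACA
row	H	CAGCGGCT
column	1	TTCGTTGA
column	2	GGGCTTGA
column	3	TAAGGGTG
column	4	GTCCACGT
column	5	TGATAAAA
column	6	TCATAGCG
column	7	AAGTGATT
column	8	GGTACAAC
column	9	TTAAGAAG
column	10	ACCCATCT
column	11	ACAGTTCT
column	12	CAGCAACG
anchor	fwd_transposase	AACGGACGATGCGT
anchor	univ_reverse_primer	GTATGGCTGTGAGACT
anchor	rev_transposase	AAGCTCTACTCGAAA
control	H10	positive
control	H11	negative
control	H12	negative
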