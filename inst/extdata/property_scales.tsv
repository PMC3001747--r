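# Bundled physicochemical property scales of the 20 standard amino acids.
# hydrophobicity: Kyte J, Doolittle RF (1982) J Mol Biol 157:105-132 (hydropathy index)
# volume: Zamyatnin AA (1972) Prog Biophys Mol Biol 24:107-123 (residue volume, cubic Angstrom)
# charge_ph7: net side-chain charge at pH 7 (D,E = -1; K,R = +1; H treated as 0)
# polarity: Grantham R (1974) Science 185:862-864 (polarity p)
# flexibility: Vihinen M, Torkkila E, Riikonen P (1994) Proteins 19:141-149 (normalized B-factor)
scale	source	aa	value
hydrophobicity	Kyte-Doolittle 1982	A	1.8
hydrophobicity	Kyte-Doolittle 1982	R	-4.5
hydrophobicity	Kyte-Doolittle 1982	N	-3.5
hydrophobicity	Kyte-Doolittle 1982	D	-3.5
hydrophobicity	Kyte-Doolittle 1982	C	2.5
hydrophobicity	Kyte-Doolittle 1982	Q	-3.5
hydrophobicity	Kyte-Doolittle 1982	E	-3.5
hydrophobicity	Kyte-Doolittle 1982	G	-0.4
hydrophobicity	Kyte-Doolittle 1982	H	-3.2
hydrophobicity	Kyte-Doolittle 1982	I	4.5
hydrophobicity	Kyte-Doolittle 1982	L	3.8
hydrophobicity	Kyte-Doolittle 1982	K	-3.9
hydrophobicity	Kyte-Doolittle 1982	M	1.9
hydrophobicity	Kyte-Doolittle 1982	F	2.8
hydrophobicity	Kyte-Doolittle 1982	P	-1.6
hydrophobicity	Kyte-Doolittle 1982	S	-0.8
hydrophobicity	Kyte-Doolittle 1982	T	-0.7
hydrophobicity	Kyte-Doolittle 1982	W	-0.9
hydrophobicity	Kyte-Doolittle 1982	Y	-1.3
hydrophobicity	Kyte-Doolittle 1982	V	4.2
volume	Zamyatnin 1972	A	88.6
volume	Zamyatnin 1972	R	173.4
volume	Zamyatnin 1972	N	114.1
volume	Zamyatnin 1972	D	111.1
volume	Zamyatnin 1972	C	108.5
volume	Zamyatnin 1972	Q	143.8
volume	Zamyatnin 1972	E	138.4
volume	Zamyatnin 1972	G	60.1
volume	Zamyatnin 1972	H	153.2
volume	Zamyatnin 1972	I	166.7
volume	Zamyatnin 1972	L	166.7
volume	Zamyatnin 1972	K	168.6
volume	Zamyatnin 1972	M	162.9
volume	Zamyatnin 1972	F	189.9
volume	Zamyatnin 1972	P	112.7
volume	Zamyatnin 1972	S	89.0
volume	Zamyatnin 1972	T	116.1
volume	Zamyatnin 1972	W	227.8
volume	Zamyatnin 1972	Y	193.6
volume	Zamyatnin 1972	V	140.0
charge_ph7	side-chain net charge at pH 7	A	0
charge_ph7	side-chain net charge at pH 7	R	1
charge_ph7	side-chain net charge at pH 7	N	0
charge_ph7	side-chain net charge at pH 7	D	-1
charge_ph7	side-chain net charge at pH 7	C	0
charge_ph7	side-chain net charge at pH 7	Q	0
charge_ph7	side-chain net charge at pH 7	E	-1
charge_ph7	side-chain net charge at pH 7	G	0
charge_ph7	side-chain net charge at pH 7	H	0
charge_ph7	side-chain net charge at pH 7	I	0
charge_ph7	side-chain net charge at pH 7	L	0
charge_ph7	side-chain net charge at pH 7	K	1
charge_ph7	side-chain net charge at pH 7	M	0
charge_ph7	side-chain net charge at pH 7	F	0
charge_ph7	side-chain net charge at pH 7	P	0
charge_ph7	side-chain net charge at pH 7	S	0
charge_ph7	side-chain net charge at pH 7	T	0
charge_ph7	side-chain net charge at pH 7	W	0
charge_ph7	side-chain net charge at pH 7	Y	0
charge_ph7	side-chain net charge at pH 7	V	0
polarity	Grantham 1974	A	8.1
polarity	Grantham 1974	R	10.5
polarity	Grantham 1974	N	11.6
polarity	Grantham 1974	D	13.0
polarity	Grantham 1974	C	5.5
polarity	Grantham 1974	Q	10.5
polarity	Grantham 1974	E	12.3
polarity	Grantham 1974	G	9.0
polarity	Grantham 1974	H	10.4
polarity	Grantham 1974	I	5.2
polarity	Grantham 1974	L	4.9
polarity	Grantham 1974	K	11.3
polarity	Grantham 1974	M	5.7
polarity	Grantham 1974	F	5.2
polarity	Grantham 1974	P	8.0
polarity	Grantham 1974	S	9.2
polarity	Grantham 1974	T	8.6
polarity	Grantham 1974	W	5.4
polarity	Grantham 1974	Y	6.2
polarity	Grantham 1974	V	5.9
flexibility	Vihinen 1994	A	0.984
flexibility	Vihinen 1994	R	1.008
flexibility	Vihinen 1994	N	1.048
flexibility	Vihinen 1994	D	1.068
flexibility	Vihinen 1994	C	0.906
flexibility	Vihinen 1994	Q	1.037
flexibility	Vihinen 1994	E	1.094
flexibility	Vihinen 1994	G	1.031
flexibility	Vihinen 1994	H	0.950
flexibility	Vihinen 1994	I	0.927
flexibility	Vihinen 1994	L	0.935
flexibility	Vihinen 1994	K	1.102
flexibility	Vihinen 1994	M	0.952
flexibility	Vihinen 1994	F	0.915
flexibility	Vihinen 1994	P	1.049
flexibility	Vihinen 1994	S	1.046
flexibility	Vihinen 1994	T	0.997
flexibility	Vihinen 1994	W	0.904
flexibility	Vihinen 1994	Y	0.929
flexibility	Vihinen 1994	V	0.931
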