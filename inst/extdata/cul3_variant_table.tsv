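case	label	gender	variant	variant_type	classification	inheritance
1	NEDAUS	M	c.900C>G p.(Tyr300∗)	nonsense	LP	de novo
2	NEDAUS	M	c.137delG p.(Arg46Leufs∗32)	frameshift	LP	de novo
3	NEDAUS	F	2266C>T p.(Arg756∗)	nonsense	LP	paternal
4	NEDAUS	M	c.1636C>T p.(Arg546∗)	nonsense	LP	NA
5	NEDAUS	M	c.1336_1337del p.(Val446Phefs∗2)	frameshift	LP	de novo
6	NEDAUS	M	c.2223dup p.(Lys742∗)	nonsense	LP	NA
7	NEDAUS	F	c.1539G>A p.(Trp513∗)	nonsense	P	de novo
8	NEDAUS	M	c.179_180delAT p.(Asn60Serfs∗8)	frameshift	LP	paternal
9	NEDAUS	M	c.1007del p.(Lys336Argfs∗13)	frameshift	LP	de novo
10	NEDAUS	F	c.2246T>C p.(Ile749Thr)	missense	LP	de novo
11	NEDAUS	M	2266C>T p.(Arg756∗)	nonsense	LP	paternal
12	NEDAUS	M	c.1020_1023dup p.(Ile342leufs∗11)	frameshift	LP	de novo
13	NEDAUS	M	c.540-2A>G p.?	splice site	LP	de novo
14	NEDAUS	M	c.1654C>T p.(Arg552∗)	nonsense	P	de novo
15	NEDAUS	F	c.1777C>T p.(Gln593∗)	nonsense	LP	de novo
16	NEDAUS	F	c.493_494del p.(Leu165Ilefs∗37)	frameshift	LP	de novo
17	NEDAUS	M	c.978del p.(Ala327Leufs∗22)	frameshift	LP	de novo
18	NEDAUS_VUS_positive	M	arr[GRCh37] 2q36.1q36.2(224877730_225811469)x1	deletion	VUS	NA
19	NEDAUS_VUS	F	c.854T>C p.(Val285Ala)	missense	VUS	de novo
20	NEDAUS_VUS	M	C.223A>C p.(Thr75Pro)	missense	VUS	paternal
21	NEDAUS_VUS	F	c.443G>A p.(Arg148Gln)	missense	VUS	de novo
22	NEDAUS_VUS	F	c.223A>C p.(Thr75Pro)	missense	VUS	de novo
23	NEDAUS_negative	M	c.1207-3C>TC>T p.?	splice site	LP	de novo
24	NEDAUS_negative	F	c.1708-1G>A p.?	splice site	LP	de novo
25	NEDAUS_negative	F	c.1526del p.(Thr509fs)	frameshift	LP	de novo
26	NEDAUS_negative	F	c.856delC p.(His286Ilefs∗3)	frameshift	LP	de novo
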