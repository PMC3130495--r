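residue	atom	element	charge	lone_pairs	donor_h
A	CA	C	0	0	0
A	CB	C	-0.18	0	0
A	HB1	H	0.06	0	0
A	HB2	H	0.06	0	0
A	HB3	H	0.06	0	0
R	CA	C	-0.26	0	0
R	CB	C	-0.12	0	0
R	HB1	H	0.06	0	0
R	HB2	H	0.06	0	0
R	CG	C	-0.12	0	0
R	HG1	H	0.06	0	0
R	HG2	H	0.06	0	0
R	CD	C	0.09	0	0
R	HD1	H	0.06	0	0
R	HD2	H	0.06	0	0
R	NE	N	-0.53	0	0
R	HE	H	0.35	0	1
R	CZ	C	0.81	0	0
R	NH1	N	-0.69	0	0
R	HH11	H	0.45	0	1
R	HH12	H	0.45	0	1
R	NH2	N	-0.69	0	0
R	HH21	H	0.45	0	1
R	HH22	H	0.45	0	1
N	CA	C	0	0	0
N	CB	C	-0.12	0	0
N	HB1	H	0.06	0	0
N	HB2	H	0.06	0	0
N	CG	C	0.55	0	0
N	OD1	O	-0.55	2	0
N	ND2	N	-0.82	0	0
N	HD21	H	0.41	0	1
N	HD22	H	0.41	0	1
D	CA	C	-0.01	0	0
D	CB	C	-0.21	0	0
D	HB1	H	0.06	0	0
D	HB2	H	0.06	0	0
D	CG	C	0.7	0	0
D	OD1	O	-0.8	2	0
D	OD2	O	-0.8	2	0
C	CA	C	0.11	0	0
C	CB	C	-0.06	0	0
C	HB1	H	0.06	0	0
C	HB2	H	0.06	0	0
C	SG	S	-0.33	2	0
C	HG1	H	0.16	0	1
Q	CA	C	0	0	0
Q	CB	C	-0.12	0	0
Q	HB1	H	0.06	0	0
Q	HB2	H	0.06	0	0
Q	CG	C	-0.12	0	0
Q	HG1	H	0.06	0	0
Q	HG2	H	0.06	0	0
Q	CD	C	0.55	0	0
Q	OE1	O	-0.55	2	0
Q	NE2	N	-0.82	0	0
Q	HE21	H	0.41	0	1
Q	HE22	H	0.41	0	1
E	CA	C	-0.01	0	0
E	CB	C	-0.12	0	0
E	HB1	H	0.06	0	0
E	HB2	H	0.06	0	0
E	CG	C	-0.21	0	0
E	HG1	H	0.06	0	0
E	HG2	H	0.06	0	0
E	CD	C	0.7	0	0
E	OE1	O	-0.8	2	0
E	OE2	O	-0.8	2	0
G	CA	C	-0.06	0	0
G	HA2	H	0.06	0	0
H	CA	C	0.02	0	0
H	CB	C	-0.12	0	0
H	HB1	H	0.06	0	0
H	HB2	H	0.06	0	0
H	CG	C	0.18	0	0
H	ND1	N	-0.56	1	0
H	CE1	C	0.25	0	0
H	HE11	H	0.13	0	0
H	NE2	N	-0.53	0	0
H	HE2	H	0.38	0	1
H	CD2	C	0.02	0	0
H	HD21	H	0.11	0	0
I	CA	C	0	0	0
I	CB	C	-0.06	0	0
I	HB1	H	0.06	0	0
I	CG1	C	-0.12	0	0
I	HG11	H	0.06	0	0
I	HG12	H	0.06	0	0
I	CG2	C	-0.18	0	0
I	HG21	H	0.06	0	0
I	HG22	H	0.06	0	0
I	HG23	H	0.06	0	0
I	CD1	C	-0.18	0	0
I	HD11	H	0.06	0	0
I	HD12	H	0.06	0	0
I	HD13	H	0.06	0	0
L	CA	C	0	0	0
L	CB	C	-0.12	0	0
L	HB1	H	0.06	0	0
L	HB2	H	0.06	0	0
L	CG	C	-0.06	0	0
L	HG1	H	0.06	0	0
L	CD1	C	-0.18	0	0
L	HD11	H	0.06	0	0
L	HD12	H	0.06	0	0
L	HD13	H	0.06	0	0
L	CD2	C	-0.18	0	0
L	HD21	H	0.06	0	0
L	HD22	H	0.06	0	0
L	HD23	H	0.06	0	0
K	CA	C	-0.02	0	0
K	CB	C	-0.12	0	0
K	HB1	H	0.06	0	0
K	HB2	H	0.06	0	0
K	CG	C	-0.12	0	0
K	HG1	H	0.06	0	0
K	HG2	H	0.06	0	0
K	CD	C	-0.12	0	0
K	HD1	H	0.06	0	0
K	HD2	H	0.06	0	0
K	CE	C	0.21	0	0
K	HE1	H	0.06	0	0
K	HE2	H	0.06	0	0
K	NZ	N	-0.3	0	0
K	HZ1	H	0.33	0	1
K	HZ2	H	0.33	0	1
K	HZ3	H	0.33	0	1
M	CA	C	0.1	0	0
M	CB	C	-0.12	0	0
M	HB1	H	0.06	0	0
M	HB2	H	0.06	0	0
M	CG	C	0.04	0	0
M	HG1	H	0.06	0	0
M	HG2	H	0.06	0	0
M	SD	S	-0.34	2	0
M	CE	C	-0.1	0	0
M	HE1	H	0.06	0	0
M	HE2	H	0.06	0	0
M	HE3	H	0.06	0	0
F	CA	C	0	0	0
F	CB	C	-0.12	0	0
F	HB1	H	0.06	0	0
F	HB2	H	0.06	0	0
F	CG	C	0	0	0
F	CD1	C	-0.115	0	0
F	HD11	H	0.115	0	0
F	CD2	C	-0.115	0	0
F	HD21	H	0.115	0	0
F	CE1	C	-0.115	0	0
F	HE11	H	0.115	0	0
F	CE2	C	-0.115	0	0
F	HE21	H	0.115	0	0
F	CZ	C	-0.115	0	0
F	HZ1	H	0.115	0	0
P	CA	C	0.12	0	0
P	CB	C	-0.12	0	0
P	HB1	H	0.06	0	0
P	HB2	H	0.06	0	0
P	CG	C	-0.12	0	0
P	HG1	H	0.06	0	0
P	HG2	H	0.06	0	0
P	CD	C	0.02	0	0
P	HD1	H	0.06	0	0
P	HD2	H	0.06	0	0
P	N	N	-0.26	0	0
S	CA	C	-0.01	0	0
S	CB	C	0.15	0	0
S	HB1	H	0.06	0	0
S	HB2	H	0.06	0	0
S	OG	O	-0.68	2	0
S	HG	H	0.42	0	1
T	CA	C	-0.01	0	0
T	CB	C	0.21	0	0
T	HB1	H	0.06	0	0
T	OG1	O	-0.68	2	0
T	HG1	H	0.42	0	1
T	CG2	C	-0.18	0	0
T	HG21	H	0.06	0	0
T	HG22	H	0.06	0	0
T	HG23	H	0.06	0	0
W	CA	C	-0.275	0	0
W	CB	C	-0.12	0	0
W	HB1	H	0.06	0	0
W	HB2	H	0.06	0	0
W	CG	C	-0.03	0	0
W	CD1	C	0.06	0	0
W	HD11	H	0.115	0	0
W	NE1	N	-0.34	0	0
W	HE1	H	0.34	0	1
W	CE2	C	0.13	0	0
W	CD2	C	0	0	0
W	CE3	C	-0.115	0	0
W	HE31	H	0.115	0	0
W	CZ3	C	-0.115	0	0
W	HZ31	H	0.115	0	0
W	CH2	C	-0.115	0	0
W	HH21	H	0.115	0	0
W	CZ2	C	-0.115	0	0
W	HZ21	H	0.115	0	0
Y	CA	C	0.11	0	0
Y	CB	C	-0.12	0	0
Y	HB1	H	0.06	0	0
Y	HB2	H	0.06	0	0
Y	CG	C	0	0	0
Y	CD1	C	-0.115	0	0
Y	HD11	H	0.115	0	0
Y	CD2	C	-0.115	0	0
Y	HD21	H	0.115	0	0
Y	CE1	C	-0.115	0	0
Y	HE11	H	0.115	0	0
Y	CE2	C	-0.115	0	0
Y	HE21	H	0.115	0	0
Y	CZ	C	0.15	0	0
Y	OH	O	-0.68	2	0
Y	HH	H	0.42	0	1
V	CA	C	0	0	0
V	CB	C	-0.06	0	0
V	HB1	H	0.06	0	0
V	CG1	C	-0.18	0	0
V	HG11	H	0.06	0	0
V	HG12	H	0.06	0	0
V	HG13	H	0.06	0	0
V	CG2	C	-0.18	0	0
V	HG21	H	0.06	0	0
V	HG22	H	0.06	0	0
V	HG23	H	0.06	0	0
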