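residue	atom1	atom2	length
A	CA	CB	1.53
A	CB	HB1	1.09
A	CB	HB2	1.09
A	CB	HB3	1.09
R	CA	CB	1.53
R	CB	HB1	1.09
R	CB	HB2	1.09
R	CB	CG	1.53
R	CG	HG1	1.09
R	CG	HG2	1.09
R	CG	CD	1.53
R	CD	HD1	1.09
R	CD	HD2	1.09
R	CD	NE	1.46
R	NE	HE	1.01
R	NE	CZ	1.33
R	CZ	NH1	1.33
R	CZ	NH2	1.33
R	NH1	HH11	1.01
R	NH1	HH12	1.01
R	NH2	HH21	1.01
R	NH2	HH22	1.01
N	CA	CB	1.53
N	CB	HB1	1.09
N	CB	HB2	1.09
N	CB	CG	1.53
N	CG	OD1	1.23
N	CG	ND2	1.33
N	ND2	HD21	1.01
N	ND2	HD22	1.01
D	CA	CB	1.53
D	CB	HB1	1.09
D	CB	HB2	1.09
D	CB	CG	1.53
D	CG	OD1	1.25
D	CG	OD2	1.25
C	CA	CB	1.53
C	CB	HB1	1.09
C	CB	HB2	1.09
C	CB	SG	1.81
C	SG	HG1	1.34
Q	CA	CB	1.53
Q	CB	HB1	1.09
Q	CB	HB2	1.09
Q	CB	CG	1.53
Q	CG	HG1	1.09
Q	CG	HG2	1.09
Q	CG	CD	1.53
Q	CD	OE1	1.23
Q	CD	NE2	1.33
Q	NE2	HE21	1.01
Q	NE2	HE22	1.01
E	CA	CB	1.53
E	CB	HB1	1.09
E	CB	HB2	1.09
E	CB	CG	1.53
E	CG	HG1	1.09
E	CG	HG2	1.09
E	CG	CD	1.53
E	CD	OE1	1.25
E	CD	OE2	1.25
G	CA	HA2	1.09
H	CA	CB	1.53
H	CB	HB1	1.09
H	CB	HB2	1.09
H	CB	CG	1.51
H	CG	ND1	1.38
H	ND1	CE1	1.32
H	CE1	NE2	1.33
H	NE2	CD2	1.37
H	CD2	CG	1.36
H	CE1	HE11	1.08
H	NE2	HE2	1.01
H	CD2	HD21	1.08
I	CA	CB	1.53
I	CB	HB1	1.09
I	CB	CG1	1.53
I	CG1	HG11	1.09
I	CG1	HG12	1.09
I	CB	CG2	1.53
I	CG2	HG21	1.09
I	CG2	HG22	1.09
I	CG2	HG23	1.09
I	CG1	CD1	1.53
I	CD1	HD11	1.09
I	CD1	HD12	1.09
I	CD1	HD13	1.09
L	CA	CB	1.53
L	CB	HB1	1.09
L	CB	HB2	1.09
L	CB	CG	1.53
L	CG	HG1	1.09
L	CG	CD1	1.53
L	CD1	HD11	1.09
L	CD1	HD12	1.09
L	CD1	HD13	1.09
L	CG	CD2	1.53
L	CD2	HD21	1.09
L	CD2	HD22	1.09
L	CD2	HD23	1.09
K	CA	CB	1.53
K	CB	HB1	1.09
K	CB	HB2	1.09
K	CB	CG	1.53
K	CG	HG1	1.09
K	CG	HG2	1.09
K	CG	CD	1.53
K	CD	HD1	1.09
K	CD	HD2	1.09
K	CD	CE	1.53
K	CE	HE1	1.09
K	CE	HE2	1.09
K	CE	NZ	1.49
K	NZ	HZ1	1.01
K	NZ	HZ2	1.01
K	NZ	HZ3	1.01
M	CA	CB	1.53
M	CB	HB1	1.09
M	CB	HB2	1.09
M	CB	CG	1.53
M	CG	HG1	1.09
M	CG	HG2	1.09
M	CG	SD	1.81
M	SD	CE	1.81
M	CE	HE1	1.09
M	CE	HE2	1.09
M	CE	HE3	1.09
F	CA	CB	1.53
F	CB	HB1	1.09
F	CB	HB2	1.09
F	CB	CG	1.51
F	CG	CD1	1.39
F	CG	CD2	1.39
F	CD1	CE1	1.39
F	CD2	CE2	1.39
F	CE1	CZ	1.39
F	CE2	CZ	1.39
F	CD1	HD11	1.08
F	CD2	HD21	1.08
F	CE1	HE11	1.08
F	CE2	HE21	1.08
F	CZ	HZ1	1.08
P	CA	CB	1.53
P	CB	HB1	1.09
P	CB	HB2	1.09
P	CB	CG	1.53
P	CG	HG1	1.09
P	CG	HG2	1.09
P	CG	CD	1.53
P	CD	HD1	1.09
P	CD	HD2	1.09
P	CD	N	1.47
P	N	CA	1.47
S	CA	CB	1.53
S	CB	HB1	1.09
S	CB	HB2	1.09
S	CB	OG	1.43
S	OG	HG	0.96
T	CA	CB	1.53
T	CB	HB1	1.09
T	CB	OG1	1.43
T	OG1	HG1	0.96
T	CB	CG2	1.53
T	CG2	HG21	1.09
T	CG2	HG22	1.09
T	CG2	HG23	1.09
W	CA	CB	1.53
W	CB	HB1	1.09
W	CB	HB2	1.09
W	CB	CG	1.51
W	CG	CD1	1.37
W	CD1	NE1	1.38
W	NE1	CE2	1.37
W	CE2	CD2	1.41
W	CG	CD2	1.43
W	CD2	CE3	1.4
W	CE3	CZ3	1.39
W	CZ3	CH2	1.4
W	CH2	CZ2	1.39
W	CZ2	CE2	1.4
W	CD1	HD11	1.08
W	NE1	HE1	1.01
W	CE3	HE31	1.08
W	CZ3	HZ31	1.08
W	CH2	HH21	1.08
W	CZ2	HZ21	1.08
Y	CA	CB	1.53
Y	CB	HB1	1.09
Y	CB	HB2	1.09
Y	CB	CG	1.51
Y	CG	CD1	1.39
Y	CG	CD2	1.39
Y	CD1	CE1	1.39
Y	CD2	CE2	1.39
Y	CE1	CZ	1.39
Y	CE2	CZ	1.39
Y	CD1	HD11	1.08
Y	CD2	HD21	1.08
Y	CE1	HE11	1.08
Y	CE2	HE21	1.08
Y	CZ	OH	1.37
Y	OH	HH	0.96
V	CA	CB	1.53
V	CB	HB1	1.09
V	CB	CG1	1.53
V	CG1	HG11	1.09
V	CG1	HG12	1.09
V	CG1	HG13	1.09
V	CB	CG2	1.53
V	CG2	HG21	1.09
V	CG2	HG22	1.09
V	CG2	HG23	1.09
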