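residue	a	b	c	d	e	f	g
A	1.60	1.00	1.00	1.40	1.00	1.00	1.00
R	0.70	1.10	1.10	0.60	1.30	1.10	1.40
N	0.60	1.10	1.10	0.60	1.10	1.10	1.10
D	0.40	1.10	1.10	0.40	1.10	1.10	1.10
C	0.90	0.60	0.60	0.80	0.60	0.60	0.60
Q	0.80	1.30	1.30	0.70	1.30	1.30	1.30
E	0.60	1.40	1.30	0.60	1.80	1.20	1.50
G	0.30	0.70	0.70	0.30	0.70	0.70	0.70
H	0.60	0.90	0.90	0.60	0.90	0.90	0.90
I	2.90	0.80	0.80	2.20	0.80	0.80	0.80
L	3.20	0.90	0.90	3.60	0.90	0.90	0.90
K	0.70	1.20	1.20	0.60	1.50	1.20	1.60
M	2.40	0.90	0.90	2.00	0.90	0.90	0.90
F	1.40	0.60	0.60	1.20	0.60	0.60	0.60
P	0.05	0.05	0.05	0.05	0.05	0.05	0.05
S	0.70	1.00	1.00	0.70	1.00	1.00	1.00
T	0.70	1.00	1.00	0.70	1.00	1.00	1.00
W	0.90	0.60	0.60	0.80	0.60	0.60	0.60
Y	1.00	0.80	0.80	0.90	0.80	0.80	0.80
V	2.20	0.80	0.80	1.80	0.80	0.80	0.80
X	1.00	1.00	1.00	1.00	1.00	1.00	1.00
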