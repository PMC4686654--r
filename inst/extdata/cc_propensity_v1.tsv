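# ccruler heptad propensity table, version 1.
# Curated synthetic table encoding canonical heptad-position preferences of
# long two-stranded coiled-coils: aliphatic residues favoured at core
# positions a/d, charged/polar residues at flanking e/g, mild polar
# preferences at surface b/c/f, proline strongly disfavoured everywhere.
# Values are relative propensities (dimensionless, >0); only relative
# scores are meaningful and the table can be swapped via propensity_table().
aa	a	b	c	d	e	f	g
A	1.20	1.30	1.30	1.00	1.00	1.30	1.00
C	0.60	0.50	0.50	0.50	0.40	0.50	0.40
D	0.30	1.00	1.00	0.40	0.90	1.00	0.90
E	0.40	1.40	1.40	0.50	2.20	1.40	2.20
F	1.10	0.60	0.60	0.90	0.40	0.60	0.40
G	0.20	0.40	0.40	0.20	0.30	0.40	0.30
H	0.60	0.80	0.80	0.60	0.70	0.80	0.70
I	2.60	0.60	0.60	1.40	0.60	0.60	0.60
K	0.50	1.40	1.40	0.40	1.90	1.40	1.90
L	3.20	0.90	0.90	3.00	0.90	0.90	0.90
M	2.20	0.80	0.80	1.60	0.70	0.80	0.70
N	0.80	1.00	1.00	0.60	0.80	1.00	0.80
P	0.02	0.05	0.05	0.02	0.03	0.05	0.03
Q	0.80	1.30	1.30	0.80	1.60	1.30	1.60
R	0.60	1.20	1.20	0.50	1.70	1.20	1.70
S	0.60	1.00	1.00	0.60	0.70	1.00	0.70
T	0.70	0.90	0.90	0.60	0.70	0.90	0.70
V	1.80	0.60	0.60	1.10	0.50	0.60	0.50
W	0.60	0.40	0.40	0.50	0.30	0.40	0.30
Y	0.80	0.70	0.70	0.70	0.50	0.70	0.50
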