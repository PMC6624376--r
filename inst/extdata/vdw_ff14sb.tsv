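# van der Waals parameters by SYBYL atom type, transcribed from the
# published AMBER ff14SB parameter set (GAFF values for halogens).
# r0 is Rmin/2 in Angstrom (pair minimum for a like pair sits at 2*r0);
# eps is the well depth in kcal/mol. Single-token rows (no dot) are
# element-level fallbacks used when the full SYBYL type has no entry.
# The SYBYL -> AMBER type correspondence is an approximation documented
# in the package vignette.
# columns: sybyl_type	amber_type	r0	eps
C.3	CT	1.9080	0.1094
C.2	C	1.9080	0.0860
C.1	CZ	1.9080	0.0860
C.ar	CA	1.9080	0.0860
C.cat	C	1.9080	0.0860
N.1	N	1.8240	0.1700
N.2	N	1.8240	0.1700
N.3	N3	1.8240	0.1700
N.4	N3	1.8240	0.1700
N.ar	NB	1.8240	0.1700
N.am	N	1.8240	0.1700
N.pl3	N	1.8240	0.1700
O.2	O	1.6612	0.2100
O.3	OH	1.7210	0.2104
O.co2	O2	1.6612	0.2100
O.spc	OW	1.7683	0.1520
O.t3p	OW	1.7683	0.1520
S.3	S	2.0000	0.2500
S.2	S	2.0000	0.2500
S.o	S	2.0000	0.2500
S.o2	S	2.0000	0.2500
P.3	P	2.1000	0.2000
H	HC	1.4870	0.0157
H.spc	HW	1.0000	0.0000
H.t3p	HW	1.0000	0.0000
F	F	1.7500	0.0610
Cl	CL	1.9480	0.2650
Br	BR	2.2200	0.3200
I	I	2.3500	0.4000
C	C	1.9080	0.0860
N	N	1.8240	0.1700
O	O	1.6612	0.2100
S	S	2.0000	0.2500
P	P	2.1000	0.2000
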