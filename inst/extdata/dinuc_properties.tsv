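# RNA dinucleotide step properties (16 dinucleotides x 10 properties).
# Provenance, per property:
#   shift, slide, rise (Angstrom) and tilt, roll, twist (degrees):
#     transcribed A-form RNA base-pair step averages from crystallographic
#     helical-parameter surveys of naked RNA duplexes; values are rounded
#     survey means, not tied to a specific database record ID.
#   enthalpy (kcal/mol), entropy (cal/(mol*K)), free_energy (kcal/mol at 37C):
#     Watson-Crick nearest-neighbor thermodynamic parameters for RNA duplexes
#     from optical melting (Xia et al. 1998, Biochemistry 37:14719).
#     Each step equals its reverse complement, as in the source table.
#   hydrophilicity (dimensionless):
#     dinucleoside monophosphate hydrophilicity scale after Weber & Lacey
#     (1978), as commonly tabulated for RNA dinucleotides.
# Dinucleotides are written 5'->3' over the RNA alphabet {A,C,G,U}.
dinucleotide	shift	slide	rise	tilt	roll	twist	enthalpy	entropy	free_energy	hydrophilicity
AA	-0.08	-1.27	3.18	-0.8	7.0	31.5	-6.82	-19.0	-0.93	0.023
AC	0.23	-1.43	3.24	0.8	4.8	32.3	-11.40	-29.5	-2.24	0.083
AG	-0.04	-1.50	3.30	0.5	8.5	30.5	-10.48	-27.1	-2.08	0.035
AU	-0.06	-1.36	3.24	1.1	7.1	33.0	-9.38	-26.7	-1.10	0.090
CA	0.11	-1.46	3.09	1.0	9.9	31.9	-10.44	-26.9	-2.11	0.118
CC	-0.01	-1.78	3.32	0.6	8.7	33.7	-13.39	-32.7	-3.26	0.349
CG	0.30	-1.89	3.30	-0.1	12.1	31.3	-10.64	-26.7	-2.36	0.193
CU	-0.07	-1.52	3.29	0.2	7.8	31.1	-10.48	-27.1	-2.08	0.378
GA	0.07	-1.70	3.38	-1.3	9.4	34.4	-12.44	-32.5	-2.35	0.048
GC	0.07	-1.39	3.22	0.0	6.1	34.9	-14.88	-36.9	-3.42	0.087
GG	-0.02	-1.78	3.32	0.7	12.1	30.7	-13.39	-32.7	-3.26	0.160
GU	0.18	-1.48	3.21	0.6	5.4	32.0	-11.40	-29.5	-2.24	0.160
UA	-0.02	-1.45	3.26	-0.4	10.7	32.8	-7.69	-20.5	-1.33	0.112
UC	0.10	-1.65	3.35	-0.9	8.9	33.9	-12.44	-32.5	-2.35	0.359
UG	0.09	-1.41	3.15	0.8	10.3	31.6	-10.44	-26.9	-2.11	0.224
UU	-0.05	-1.30	3.20	-0.6	6.6	31.8	-6.82	-19.0	-0.93	0.389
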