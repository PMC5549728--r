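# Reference residue-contact fingerprints for the three hyaluronan binding
# modes of the CD44 hyaluronan-binding domain (human numbering, UniProt
# P16070 after signal-peptide cleavage; HABD = residues 20-169).
# Values are the percentage of simulation frames in which any heavy atom of
# the residue lies within 0.6 nm of the ligand, averaged over replicas;
# *_se columns are standard errors over replicas (0 where replicas agreed).
residue	crystallographic	crystallographic_se	parallel	parallel_se	upright	upright_se
N25	52.3	0.4	89.7	0.8	0.0	0
R29	2.1	0.7	1.1	1.1	11.2	11.2
K38	0.0	0	6.9	4.0	73.4	19.6
G40	9.5	1.5	100.0	0	39.5	23.6
R41	100.0	0	100.0	0	92.2	4.9
Y42	100.0	0	100.0	0	99.5	0.4
S43	6.0	6.0	66.1	17.6	98.0	1.3
I44	0.3	0.3	1.9	1.3	62.5	18.1
N57	0.0	0	0.0	0	20.4	20.4
K68	0.0	0	0.0	0	0.0	0
T76	95.1	0.9	2.1	2.1	51.1	17.6
C77	100.0	0	33.1	15.5	90.8	2.7
R78	100.0	0	100.0	0	92.8	3.3
Y79	100.0	0	85.2	8.2	93.4	3.2
G80	0.1	0.1	0.0	0	0.1	0.1
I88	100.0	0	10.3	3.4	78.7	9.0
N94	77.2	2.5	2.5	2.5	26.5	7.9
I96	100.0	0	16.5	7.5	96.9	0.8
C97	100.0	0	2.9	2.9	93.1	1.2
A98	100.0	0	41.9	15.3	89.4	4.7
A99	100.0	0	10.2	4.6	73.7	19.3
N100	13.2	2.5	1.5	1.2	30.7	12.8
N101	47.8	10.7	1.6	0.0	30.3	14.6
Y105	89.6	5.6	46.8	15.1	36.3	14.6
I106	35.3	13.7	18.9	10.2	0.5	0.5
L107	99.9	0.1	91.8	5.5	63.9	24.2
N110	92.1	5.7	100.0	0	13.6	7.4
D115	7.8	2.7	93.9	3.0	20.7	18.4
N120	0.0	0	0.0	0	17.5	17.5
N149	37.1	4.5	36.5	20.3	0.0	0
R150	88.0	2.7	37.0	28.5	0.0	0
D151	68.1	7.8	37.4	26.2	0.0	0
G152	61.9	8.6	65.2	20.3	0.0	0
R154	3.2	0.5	81.0	13.7	0.1	0.1
Y155	1.2	0.9	44.2	22.1	0.0	0
K158	0.0	0	17.0	11.9	35.9	18.2
R162	0.8	0.4	0.0	0	98.1	1.0
N164	10.7	7.6	0.3	0.1	68.1	18.8
E166	16.0	9.3	0.4	0.4	72.4	19.1
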