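channel	row	col
Fp1	0	1
Fp2	0	3
F7	1	0
F3	1	1
Fz	1	2
F4	1	3
F8	1	4
T3	2	0
C3	2	1
Cz	2	2
C4	2	3
T4	2	4
T5	3	0
P3	3	1
Pz	3	2
P4	3	3
T6	3	4
O1	4	1
O2	4	3
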