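from	to
Fp1	Fp2
Fp1	F7
Fp1	F3
Fp1	Fz
Fp2	Fz
Fp2	F4
Fp2	F8
F7	F3
F7	FC5
F7	T7
F3	Fz
F3	FC5
F3	FC1
Fz	F4
Fz	FC1
Fz	FC2
F4	F8
F4	FC2
F4	FC6
F8	FC6
F8	T8
FC5	T7
FC5	C3
FC5	FC1
FC1	C3
FC1	Cz
FC1	FC2
FC2	Cz
FC2	C4
FC6	C4
FC6	T8
T7	TP9
T7	C3
T7	CP5
C3	Cz
C3	CP5
C3	CP1
Cz	C4
Cz	CP1
Cz	CP2
C4	CP2
C4	CP6
C4	T8
T8	CP6
T8	TP10
TP9	P7
CP5	P7
CP5	P3
CP5	CP1
CP1	P3
CP1	Pz
CP1	CP2
CP2	Pz
CP2	P4
CP6	P4
CP6	P8
CP6	TP10
TP10	P8
P7	PO9
P7	P3
P3	Pz
P3	O1
Pz	P4
Pz	Oz
P4	P8
P4	O2
P8	PO10
PO9	O1
O1	Oz
Oz	O2
O2	PO10
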