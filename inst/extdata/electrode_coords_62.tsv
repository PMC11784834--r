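label	x	y
FP1	-0.3	0.92
FPZ	0	0.92
FP2	0.3	0.92
AF3	-0.32	0.74
AF4	0.32	0.74
F7	-0.8352	0.55
F5	-0.6264	0.55
F3	-0.4176	0.55
F1	-0.2088	0.55
FZ	0	0.55
F2	0.2088	0.55
F4	0.4176	0.55
F6	0.6264	0.55
F8	0.8352	0.55
FT7	-0.96	0.28
FC5	-0.72	0.28
FC3	-0.48	0.28
FC1	-0.24	0.28
FCZ	0	0.28
FC2	0.24	0.28
FC4	0.48	0.28
FC6	0.72	0.28
FT8	0.96	0.28
T7	-1	0
C5	-0.75	0
C3	-0.5	0
C1	-0.25	0
CZ	0	0
C2	0.25	0
C4	0.5	0
C6	0.75	0
T8	1	0
TP7	-0.96	-0.28
CP5	-0.72	-0.28
CP3	-0.48	-0.28
CP1	-0.24	-0.28
CPZ	0	-0.28
CP2	0.24	-0.28
CP4	0.48	-0.28
CP6	0.72	-0.28
TP8	0.96	-0.28
P7	-0.8352	-0.55
P5	-0.6264	-0.55
P3	-0.4176	-0.55
P1	-0.2088	-0.55
PZ	0	-0.55
P2	0.2088	-0.55
P4	0.4176	-0.55
P6	0.6264	-0.55
P8	0.8352	-0.55
PO7	-0.6726	-0.74
PO5	-0.4486	-0.74
PO3	-0.224	-0.74
POZ	0	-0.74
PO4	0.224	-0.74
PO6	0.4486	-0.74
PO8	0.6726	-0.74
CB1	-0.55	-0.98
O1	-0.3	-0.92
OZ	0	-0.92
O2	0.3	-0.92
CB2	0.55	-0.98
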