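aa	C	H	N	O	S
A	1	3	0	0	0
R	4	10	3	0	0
N	2	4	1	1	0
D	2	3	0	2	0
C	1	3	0	0	1
Q	3	6	1	1	0
E	3	5	0	2	0
G	0	1	0	0	0
H	4	5	2	0	0
I	4	9	0	0	0
L	4	9	0	0	0
K	4	10	1	0	0
M	3	7	0	0	1
F	7	7	0	0	0
P	3	5	0	0	0
S	1	3	0	1	0
T	2	5	0	1	0
W	9	8	1	0	0
Y	7	7	0	1	0
V	3	7	0	0	0
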