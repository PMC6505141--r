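TG14	1	0	0	0	1
TG14	2	0	0	0	1
TG14	3	1	2	0	1
TG14	4	1	2	0	1
TG14	5	1	2	0	1
TG14	6	0	0	0	1
TG14	7	0	0	0	1
TG14	8	0	0	0	1
TG14	9	3	6	0	1
TG14	10	3	6	0	1
TG14	11	4	7	0	1
TG14	12	4	7	0	1
TG14	13	5	8	0	1
TG14	14	5	8	0	1
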