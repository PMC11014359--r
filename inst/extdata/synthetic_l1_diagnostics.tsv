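reference	position	subfamily	base
L1_3end	6	L1-HS	G
L1_3end	14	L1-HS	A
L1_3end	22	L1-HS	A
L1_3end	33	L1-HS	T
L1_3end	6	L1-PA2	T
L1_3end	14	L1-PA2	A
L1_3end	22	L1-PA2	A
L1_3end	33	L1-PA2	T
L1_3end	6	L1-PA3	T
L1_3end	14	L1-PA3	C
L1_3end	22	L1-PA3	A
L1_3end	33	L1-PA3	T
L1_3end	6	L1-PA4	T
L1_3end	14	L1-PA4	C
L1_3end	22	L1-PA4	C
L1_3end	33	L1-PA4	T
L1_3end	6	L1-PA5	T
L1_3end	14	L1-PA5	C
L1_3end	22	L1-PA5	C
L1_3end	33	L1-PA5	G
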