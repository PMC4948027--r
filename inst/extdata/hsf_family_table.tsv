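gene	hsf_class	subclass	length_aa	ncr	pcr
PeuHsf-A1a	A	A1	491	63	41
PeuHsf-A1b	A	A1	423	50	38
PeuHsf-A1c	A	A1	510	67	45
PeuHsf-A1d	A	A1	523	64	41
PeuHsf-A2	A	A2	425	65	47
PeuHsf-A3	A	A3	522	82	51
PeuHsf-A4a	A	A4	404	57	43
PeuHsf-A4b	A	A4	444	64	49
PeuHsf-A4c	A	A4	427	61	45
PeuHsf-A5a	A	A5	485	63	56
PeuHsf-A5b	A	A5	489	65	57
PeuHsf-A5c	A	A5	737	82	81
PeuHsf-A6a	A	A6	358	58	43
PeuHsf-A6b	A	A6	331	56	41
PeuHsf-A7a	A	A7	355	55	45
PeuHsf-A7b	A	A7	359	54	47
PeuHsf-A7c	A	A7	359	54	47
PeuHsf-A8	A	A8	392	66	37
PeuHsf-A9	A	A9	501	76	58
PeuHsf-B1	B	B1	288	51	35
PeuHsf-B2a	B	B2	294	44	34
PeuHsf-B2b	B	B2	340	47	35
PeuHsf-B2c	B	B2	287	47	37
PeuHsf-B2d	B	B2	294	44	34
PeuHsf-B3	B	B3	228	37	38
PeuHsf-B4a	B	B4	364	32	34
PeuHsf-B4b	B	B4	271	34	31
PeuHsf-B4c	B	B4	368	33	34
PeuHsf-B4d	B	B4	270	32	32
PeuHsf-B5a	B	B5	209	26	33
PeuHsf-B5b	B	B5	207	22	30
PeuHsf-C1	C	C1	338	40	37
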