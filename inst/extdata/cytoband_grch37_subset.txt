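chr3	23900000	26400000	p24.2	.
chr3	58600000	63700000	p14.2	.
chr3	148900000	160700000	q25	.
chr3	182700000	187900000	q27	.
chr10	52900000	70600000	q21	.
chr10	70600000	74900000	q22.1	.
chr10	89500000	97000000	q23.3	.
chr10	99300000	101900000	q24.2	.
chr10	111900000	114900000	q25.2	.
chr10	119100000	127500000	q26.1	.
chr16	14800000	16800000	p13.11	.
chr16	24200000	28100000	p12.1	.
chr16	66700000	70800000	q22.1	.
chr16	79200000	81700000	q23.2	.
chr17	10700000	16000000	p12	.
chr17	57600000	58300000	q23.1	.
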