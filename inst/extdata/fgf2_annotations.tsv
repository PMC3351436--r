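first	last	label
34	37	b1 and b1-b2 loop
48	52	b3 strand
62	67	b4 strand
66	71	b4 strand and b4-b5 loop
72	74	b5 strand
107	112	b8-b9 turn
128	144	b10-b12 loop
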