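# Toy reaction network: chain A -> B, branch at B, pool-dependent tail.
# id	substrates	products	direction
r1	A	B	forward
r2	B	C	forward
r3	B	D	forward
r4	C+P	E	forward
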