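id	L1	L2	L3	L4	path
c1	A	01	A	A	A01AA
c2	A	01	A	A	A01AA
c3	B	02	A	A	B02AA
c4	N	02	B	A	N02BA
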