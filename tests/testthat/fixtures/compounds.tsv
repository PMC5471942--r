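id	smiles	atc_codes
c1	NA	A01AA01
c2	NA	A01AB
c3	NA	B02BA
c4	NA	N02BA01;B01AC06
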