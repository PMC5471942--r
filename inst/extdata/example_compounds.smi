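CC(=O)OC1=CC=CC=C1C(=O)O	aspirin
CN1C=NC2=C1C(=O)N(C(=O)N2C)C	caffeine
CC(=O)NC1=CC=C(C=C1)O	paracetamol
CC(C)CC1=CC=C(C=C1)C(C)C(=O)O	ibuprofen
CCO	ethanol
CN1CCCC1C1=CC=CN=C1	nicotine
C(C1C(C(C(C(O1)O)O)O)O)O	glucose
C	methane
CC(CS)C(=O)N1CCCC1C(=O)O	captopril
CNCC(C1=CC(=C(C=C1)O)O)O	epinephrine
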