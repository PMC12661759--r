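group	charge	pka
Nterm	positive	7.5
H	positive	5.98
K	positive	10
R	positive	12
Cterm	negative	3.55
C	negative	9
D	negative	4.05
E	negative	4.45
Y	negative	10
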