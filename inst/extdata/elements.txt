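# Element symbols used by the synthetic formula grammar.
H
He
Li
Be
B
C
N
O
F
Ne
Na
Mg
Al
Si
P
S
Cl
K
Ca
Ti
Cr
Mn
Fe
Co
Ni
Cu
Zn
As
Se
Br
Mo
Ag
Cd
Sn
I
Ba
Pt
Au
Hg
Pb
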