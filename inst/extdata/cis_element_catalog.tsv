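name	iupac_pattern	functional_class
HSE	AGAANNTTCT	stress
TC-rich_repeats	ATTTTCTTCA	stress
MBS	CAACTG	stress
ARE	AAACCA	stress
LTR	CCGAAA	stress
ABRE	ACGTG	hormone
CGTCA-motif	CGTCA	hormone
TGACG-motif	TGACG	hormone
TCA-element	CCATCTTTTT	hormone
GARE-motif	TCTGTTG	hormone
TGA-element	AACGAC	hormone
P-box	CCTTTTG	hormone
circadian	CAAAGATATC	development
CAT-box	GCCACT	development
CCGTCC-box	CCGTCC	development
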