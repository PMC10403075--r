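# Apolipoprotein C-II mimetic peptide set (extended sequence dialect).
# P8 is mature human ApoC2 residues 59-79. D6PV and P33 are synthetic
# reconstructions of the bi-helical mimetic and its truncated staple-design
# scaffold: the second-helix region is the native 21-mer; the first-helix
# region is rebuilt from its documented design properties.
P8	AMSTYTGIFTDQVLSVLKGEE
APOC2_59_79	AMSTYTGIFTDQVLSVLKGEE
P6	AM{R8}TYTGIF{S5}DQVLSVLKGEE|3-10
SP1	Ac-A{Nle}{R8}TYTGIF{S5}DQVLSVLK{Sar}ee|3-10
SP2	Ac-A{Nle}{R8}TYTGIF{B5}DQVLSV{S8}K{Sar}ee|3-10|10-17
SP2a	Oct-{Aib}{Nle}{R8}TYTGIF{B5}DQVLSV{S8}K{Sar}ee|3-10|10-17
D6PV	KTYKEVFEKLRDLYSKSTAPAMSTYTGIFTDQVLSVLKGEE
NATIVE_H1	KTYLPAVDEKLRDLYSKSTA
P33	EKLRDLYSKSTAAMSTYTGIFTDQVLSVLKGEE
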