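class	consensus	both_strands
ABRE	ACGTGKC	TRUE
CE1	TGCCACCGG	TRUE
CE3	ACGCGTGTC	TRUE
DRE	RCCGAC	TRUE
SARE	TTCGACC	TRUE
WBOX	TTGACY	TRUE
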