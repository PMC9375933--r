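name	pattern	category
ABRE	ACGTG	hormone_response
TGACG-motif	TGACG	hormone_response
MBS	CAACTG	drought
LTR	CCGAAA	low_temperature
W-box	TTGACC	wounding_pathogen
Box-S	AGCCACC	wounding_pathogen
WUN-motif	AAATTTCCT	wounding_pathogen
G-box	CACGTG	light
Box-4	ATTAAT	light
CAT-box	GCCACT	development
O2-site	GATGACATGG	development
TATA-box	TATAWA	core_promoter
CAAT-box	CCAAT	core_promoter
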