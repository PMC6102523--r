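# Starter cis-element table: simplified literature consensus patterns
# (IUPAC), NOT the scanning matrices of any promoter database. Users
# should supply their own table for production scans.
name	pattern	category
TCA-element	CCATCTTTTT	hormone
TGA-element	AACGAC	hormone
GARE-motif	TCTGTTG	hormone
ABRE	ACGTG	hormone
TGACG-motif	TGACG	hormone
ARE	AAACCA	stress
MBS	CAACTG	stress
HSE	AAAAAATTTC	stress
TC-rich	ATTTTCTTCA	stress
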