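class	residues
hydrophobic	ACFILMVWY
polar	DEHKNQRST
charged	DEHKR
positively_charged	HKR
negatively_charged	DE
tiny	ACGST
small	ACDGNPSTV
aliphatic	AILV
aromatic	FHWY
amide	NQ
sulfur_containing	CM
hydroxyl_containing	STY
basic	KR
branched_chain	ILV
cyclic	FHPWY
helix_favoring	AEHKLMQ
sheet_favoring	FITVWY
turn_favoring	DGNPS
nonpolar	AFGILMPVW
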