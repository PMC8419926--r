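# Known fungal transcription-factor consensus motifs (IUPAC).
# AmyR and PrtT are the A. niger spellings reported in the primary
# literature for these regulators (AmyR: CGG-N8-(C/A)GG, written below with
# M = A/C; PrtT: CCGHCGG). CreA, PacC and the bHLH E-box are the widely
# used fungal consensus forms from the broader Aspergillus literature and
# serve as a user-extensible starting set: add rows (motif <TAB> consensus)
# to extend. Gapped motifs may be written with fixed-length gaps, e.g.
# CGG-N8-MGG.
motif	consensus
AmyR	CGG-N8-MGG
PrtT	CCGHCGG
CreA	SYGGRG
PacC	GCCARG
Ebox	CACGTG
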