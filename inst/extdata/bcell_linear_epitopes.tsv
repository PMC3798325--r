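label	kind	sequence
10A4	bcell	MSWQAYV
5F2	bcell	AQSAKFPQFKPEEM
9A7	bcell	GQAMIMGIYD
9G4	bcell	YDEPVAPG
3H8	bcell	ERLGDY
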