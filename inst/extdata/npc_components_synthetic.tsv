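id	name	substructure	synonyms
Tb927.7.970	NMD3	transport factor	NMD3
Tb927.11.3380	RanBP1	transport factor	RanBP1
Tb927.10.8650	RanBPL	transport factor	RanBPL
Tb927.11.14340	exportin 1	transport factor	XPO1;exportin1
Tb927.10.7680	GAP	transport factor	RanGAP
MEX67	MEX67	transport factor	Mex67
NUP158	NUP158	NUP76 complex associated	Nup158
NUP76	NUP76	NUP76 complex	Nup76
NUP140	NUP140	NUP76 complex	Nup140
NUP149	NUP149	NUP76 complex	Nup149
NUP96	NUP96	central scaffold	Nup96
NUP110	NUP110	nuclear basket	Nup110
NUP181	NUP181	inner ring	Nup181
NUP144	NUP144	inner ring	Nup144
NUP225	NUP225	inner ring	Nup225
NUP65	NUP65	inner ring	Nup65
NUP89	NUP89	outer ring	Nup89
NUP41	NUP41	outer ring	Nup41
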