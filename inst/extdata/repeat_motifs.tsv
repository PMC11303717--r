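unit	phase	annotation
CAG	0	Huntington disease; spinocerebellar ataxias; myotonic dystrophy type 1 (CTG strand)
CTG	0	myotonic dystrophy type 1; Fuchs endothelial corneal dystrophy
GAA	0	Friedreich ataxia
TTC	0	Friedreich ataxia (complement strand)
CGG	0	fragile X syndrome
CCG	0	fragile X syndrome (complement strand)
GAC	0	skeletal dysplasias
GGGGCC	0	C9orf72 ALS/FTD
GGCCCC	0	C9orf72 ALS/FTD (complement strand)
CCTG	0	myotonic dystrophy type 2
AATCT	0	SCA10-type pentanucleotide (complement strand)
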