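keyword	broad	specific
tail fiber	structural	tail_fiber
tail fibre	structural	tail_fiber
baseplate	structural	baseplate
portal	structural	portal
capsid	structural	capsid
neck	structural	neck
tail	structural	tail
terminase	structural	terminase
head	structural	head
dna polymerase	replication	dna_polymerase
dna primase	replication	dna_primase
primase	replication	primase
helicase	replication	helicase
ligase	replication	dna_ligase
exonuclease	replication	exonuclease
endonuclease	replication	endonuclease
recombinase	replication	recombinase
nuclease	replication	nuclease
ribonucleotide reductase	replication	ribonucleotide_reductase
thymidylate	replication	nucleotide_metabolism
nucleotide	replication	nucleotide_metabolism
methylase	replication	methylase
methyltransferase	replication	methylase
ferrochelatase	metabolism	ferrochelatase
thioredoxin	metabolism	thioredoxin
oxygenase	metabolism	oxygenase
oxidoreductase	metabolism	oxidoreductase
psba	metabolism	photosystem
photosystem	metabolism	photosystem
phosphate	metabolism	phosphate_metabolism
lysin	metabolism	lysin
lysozyme	metabolism	lysin
transcriptional regulator	regulation	transcriptional_regulator
transcription factor	regulation	transcriptional_regulator
sigma factor	regulation	sigma_factor
repressor	regulation	repressor
anti-sigma	regulation	sigma_factor
integrase	replication	integrase
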