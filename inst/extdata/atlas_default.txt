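# Default 47-region atlas (NeuroQ-style naming, one ROI per line).
# Temporal, frontal, language and subcortical regions carry their standard
# names; the remaining bilateral pairs are documented placeholders and the
# whole file can be replaced by any 47-name atlas (see ?default_atlas).
L s frontal C
R s frontal C
L m frontal C
R m frontal C
L i frontal C
R i frontal C
L sensorimotor C
R sensorimotor C
L ila temporal C
R ila temporal C
L ilp temporal C
R ilp temporal C
L sl temporal C
R sl temporal C
L pm temporal C
R pm temporal C
L associative visual C
R associative visual C
L primary visual C
R primary visual C
L parietotemporal C
R parietotemporal C
L s parietal C
R s parietal C
L i parietal C
R i parietal C
L anterior cingulate C
R anterior cingulate C
L posterior cingulate C
R posterior cingulate C
L Broca's Region
R Broca's Region
L Wernicke's Region
R Wernicke's Region
L thalamus
R thalamus
L caudate nucleus
R caudate nucleus
L lentiform nucleus
R lentiform nucleus
L hippocampus
R hippocampus
L cerebellum
R cerebellum
Midbrain
Pons
Cerebellar vermis
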