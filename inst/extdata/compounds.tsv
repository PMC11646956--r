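compound_id	name	monoisotopic_mass	pathway_ids
HMDB0000122	D-Glucose	180.06339	glycolysis
HMDB0000094	Citric acid	192.02703	tca_cycle
HMDB0000254	Succinic acid	118.02661	tca_cycle
HMDB0000134	Fumaric acid	116.01096	tca_cycle
HMDB0000156	L-Malic acid	134.02152	tca_cycle
HMDB0000208	Oxoglutaric acid	146.02152	tca_cycle
HMDB0000243	Pyruvic acid	88.01604	glycolysis;tca_cycle
HMDB0000190	L-Lactic acid	90.03169	glycolysis
HMDB0000673	Linoleic acid	280.24023	unsat_fa_biosynthesis
HMDB0000207	Oleic acid	282.25588	unsat_fa_biosynthesis
HMDB0000215	N-Acetyl-D-glucosamine	221.08994	n_glycan_biosynthesis
HMDB0000169	D-Mannose	180.06339	n_glycan_biosynthesis
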