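feature_id	phylum	effect
Aliivibrio	Proteobacteria	-0.0816
Propionibacterium	Actinobacteria	-0.0496
Orrella	Proteobacteria	-0.0444
Veillonella	Firmicutes	-0.0416
Mucinivorans	Bacteroidetes	-0.0413
Paenarthrobacter	Actinobacteria	-0.0265
Plesiomonas	Proteobacteria	-0.0224
Roseovarius	Proteobacteria	-0.018
Lactococcus	Firmicutes	-0.0165
Sulfuricella	Proteobacteria	-0.0045
Moritella	Proteobacteria	0.0096
Parabacteroides	Bacteroidetes	0.0195
Basfia	Proteobacteria	0.021
Arsenophonus	Proteobacteria	0.0224
Acidothermus	Actinobacteria	0.0282
Aureimonas	Proteobacteria	0.0508
Candidatus Arthromitus	Firmicutes	0.0653
Asaia	Proteobacteria	0.0853
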