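# Default marker-gene catalog for hot-spring microbial mat pathway profiling.
# One row per marker gene; a gene indicates exactly one pathway.
# Columns: symbol, pathway_id, pathway_name, process_class.
symbol	pathway_id	pathway_name	process_class
psaA	oxygenic_photosynthesis	Oxygenic photosynthesis	oxygenic_photosynthesis
psbA	oxygenic_photosynthesis	Oxygenic photosynthesis	oxygenic_photosynthesis
pscA	anoxygenic_phototrophy	Anoxygenic phototrophy	anoxygenic_phototrophy
pufM	anoxygenic_phototrophy	Anoxygenic phototrophy	anoxygenic_phototrophy
fmoA	anoxygenic_phototrophy	Anoxygenic phototrophy	anoxygenic_phototrophy
bchC	anoxygenic_phototrophy	Anoxygenic phototrophy	anoxygenic_phototrophy
rbcL	cbb	Calvin-Benson-Bassham cycle	carbon_fixation
mcl	hp_bicycle	3-hydroxypropionate bi-cycle	carbon_fixation
mcr	hp_bicycle	3-hydroxypropionate bi-cycle	carbon_fixation
prpE	hp_bicycle	3-hydroxypropionate bi-cycle	carbon_fixation
atoB	hh_cycle	Hydroxypropionate-hydroxybutyrate cycle	carbon_fixation
crt	hh_cycle	Hydroxypropionate-hydroxybutyrate cycle	carbon_fixation
abfD	hh_cycle	Hydroxypropionate-hydroxybutyrate cycle	carbon_fixation
sucD	hh_cycle	Hydroxypropionate-hydroxybutyrate cycle	carbon_fixation
nifH	n2_fixation	Nitrogen fixation	nitrogen_cycle
glnA	ammonia_assimilation	Ammonia assimilation	nitrogen_cycle
amt	ammonia_assimilation	Ammonia assimilation	nitrogen_cycle
amoA	ammonia_oxidation	Ammonia oxidation	nitrogen_cycle
nrfA	dnra	Dissimilatory nitrate reduction to ammonium	nitrogen_cycle
nosZ	denitrification	Denitrification	nitrogen_cycle
hzsA	anammox	Anaerobic ammonium oxidation	nitrogen_cycle
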