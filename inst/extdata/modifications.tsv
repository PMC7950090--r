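name	mass	source
None	0.000000	unimod
Oxidation	15.994915	unimod
Dioxidation	31.989829	unimod
Trioxidation	47.984744	unimod
Methylation	14.015650	unimod
Dimethylation	28.031300	unimod
Trimethylation	42.046950	unimod
Formylation	27.994915	unimod
Acetylation	42.010565	unimod
Carbamidomethylation	57.021464	unimod
Carbamylation	43.005814	unimod
Deamidation	0.984016	unimod
Amidation	-0.984016	unimod
Phosphorylation	79.966331	unimod
Sulfation	79.956815	unimod
Dehydration	-18.010565	unimod
Ammonia loss	-17.026549	unimod
Methylol	30.010565	unimod
Formaldehyde adduct	12.000000	unimod
Sodium adduct	21.981943	unimod
Potassium adduct	37.955882	unimod
TMT 10-plex	229.162932	unimod
Succinic anhydride	100.016044	unimod
HexNAc	203.079373	unimod
Hexose	162.052824	unimod
Glutathione	305.068156	unimod
Cysteinylation	119.004099	unimod
GlyGly	114.042927	unimod
Propionamide	71.037114	unimod
Hydroxamic acid from carboxylic acid	15.010899	unimod
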