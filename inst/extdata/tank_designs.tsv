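tank	volume_l	species	abundance	biomass_g
Tank1	100	Carassius auratus	6	94.35
Tank1	100	Cyprinus carpio	6	86.54
Tank1	100	Gambusia affinis	6	2.29
Tank1	100	Hypophthalmichthys molitrix	6	55.79
Tank1	100	Misgurnus anguillicaudatus	6	48.93
Tank1	100	Pseudorasbora parva	6	6.06
Tank2	100	Carassius auratus	3	47.93
Tank2	100	Cyprinus carpio	3	31.55
Tank2	100	Gambusia affinis	3	1.04
Tank2	100	Hypophthalmichthys molitrix	3	29.52
Tank2	100	Misgurnus anguillicaudatus	3	41.74
Tank2	100	Pseudorasbora parva	3	4.68
Tank3	100	Carassius auratus	4	59.26
Tank3	100	Cyprinus carpio	8	93.31
Tank3	100	Gambusia affinis	18	6.43
Tank3	100	Hypophthalmichthys molitrix	2	24.76
Tank3	100	Misgurnus anguillicaudatus	5	50.84
Tank3	100	Pseudorasbora parva	10	10.13
Tank4	100	Carassius auratus	8	118.58
Tank4	100	Cyprinus carpio	2	29.03
Tank4	100	Gambusia affinis	10	3.53
Tank4	100	Hypophthalmichthys molitrix	3	30.39
Tank4	100	Misgurnus anguillicaudatus	2	32.66
Tank4	100	Pseudorasbora parva	3	5.36
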