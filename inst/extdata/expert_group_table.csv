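group,n_experts,n_species,n_under_development,n_pending,n_validated
Bees of Colombia,12,16,,,
Aquatic birds of Colombia,48,80,2,,14
Birds of Colombia,36,277,49,156,4
Beetles,18,4,1,,
Introduced fauna,24,21,17,,1
Plants of paramo,21,212,212,,
Herps of Colombia,60,67,60,1,2
Introduced plants of Colombia,33,32,31,,
Dragonflies Colombia,5,13,11,,
Magnolias of Colombia,17,34,17,13,
Mammals of Colombia,81,52,6,1,
Orchids of Colombia,25,5,,,
Palms,8,51,46,,
Freshwater fishes,10,1,1,,
Carnivorous plants of Colombia,4,4,1,,
Plants of dry forest,28,53,48,,
Primates of Colombia,28,38,,1,37
Zamias of Colombia,17,20,,,20
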