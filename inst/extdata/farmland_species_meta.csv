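bee_species,bee_family,n_loads,n_localities,pure_pct,presence_pct,preferred_host,printed_category
Andrena alfkenella,Andrenidae,6,3,33.3,100.0,Apiaceae,broadly_oligolectic
Andrena bicolor,Andrenidae,16,7,37.5,37.5,Asteraceae,polylectic_ss
Andrena chrysosceles,Andrenidae,32,9,43.8,78.1,Apiaceae,polylectic_ss
Andrena cineraria,Andrenidae,9,3,33.3,77.8,Brassicaceae,polylectic_ss
Andrena dorsata,Andrenidae,22,9,50.0,68.2,Rosaceae,polylectic_ss
Andrena flavipes,Andrenidae,45,10,15.6,86.7,Asteraceae,polylectic_ss
Andrena florea,Andrenidae,3,2,100.0,100.0,Bryonia dioica,narrowly_oligolectic
Andrena haemorrhoa,Andrenidae,40,12,10.0,45.0,Rosaceae,polylectic_ss
Andrena labiata,Andrenidae,3,1,0.0,66.7,Caryophyllaceae,polylectic_ss
Andrena minutula,Andrenidae,15,8,20.0,60.0,Apiaceae,polylectic_ss
Andrena minutuloides,Andrenidae,8,2,100.0,100.0,Apiaceae,broadly_oligolectic
Andrena nigroaenea,Andrenidae,16,6,18.8,62.5,Apiaceae,polylectic_ss
Andrena nitida,Andrenidae,23,10,21.7,69.6,Brassicaceae,polylectic_ss
Andrena scotica,Andrenidae,18,7,55.6,77.8,Brassicaceae,polylectic_ss
Andrena semilaevis,Andrenidae,97,9,75.3,97.9,Apiaceae,polylectic_strong_preference
Andrena subopaca,Andrenidae,12,4,33.3,50.0,Apiaceae,polylectic_ss
Halictus tumulorum,Halictidae,21,10,38.1,71.4,Asteraceae,polylectic_ss
Lasioglossum albipes,Halictidae,3,2,33.3,66.7,Ranunculaceae,polylectic_ss
Lasioglossum calceatum,Halictidae,38,11,42.1,68.4,Asteraceae,polylectic_ss
Lasioglossum fulvicorne,Halictidae,7,2,57.1,71.4,Brassicaceae,polylectic_ss
Lasioglossum lativentre,Halictidae,9,3,77.8,88.9,Fabaceae,polylectic_strong_preference
Lasioglossum leucopus,Halictidae,7,6,0.0,57.1,Brassicaceae,polylectic_ss
Lasioglossum leucozonium,Halictidae,21,6,71.4,100.0,Asteraceae,polylectic_strong_preference
Lasioglossum malachurum,Halictidae,437,12,53.3,83.3,Asteraceae,polylectic_strong_preference
Lasioglossum morio,Halictidae,7,5,28.6,42.9,Brassicaceae,polylectic_ss
Lasioglossum parvulum,Halictidae,7,5,0.0,42.9,Rosaceae,polylectic_ss
Lasioglossum pauxillum,Halictidae,70,10,45.7,68.6,Asteraceae,polylectic_ss
Lasioglossum villosulum,Halictidae,25,5,100.0,100.0,Asteraceae,broadly_oligolectic
Lasioglossum xanthopus,Halictidae,7,3,42.9,85.7,Asteraceae,mesolectic
Lasioglossum zonulum,Halictidae,4,1,0.0,100.0,Rosaceae,polylectic_ss
Melitta tricincta,Melittidae,3,1,100.0,100.0,Odontites vernus,narrowly_oligolectic
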