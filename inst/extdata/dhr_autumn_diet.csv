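study_area,season,food_id,common_name,category,rf_pct,n_scats
DHR,autumn,Rubus ellipticus,Yeiselu,Buds and twigs,7.5,32
DHR,autumn,Arundinaria spp.,Nigalo,Bamboo,30.2,32
DHR,autumn,Berberis aristata,Chutro,Buds and twigs,12.5,32
DHR,autumn,Lichen,Jhayu,Lichen,13.3,32
DHR,autumn,Quercus semicarpifolia (leaf),Kharsu leaf,Leaf,6.7,32
DHR,autumn,Rhododendron spp.,Guransh,Leaf,17.0,32
DHR,autumn,Ants,Ants (Formicidae),Insect,4.3,32
DHR,autumn,Termites,Termites (Blattodea),Insect,3.1,32
DHR,autumn,Unidentified,Unidentified,,5.4,32
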