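study_area,season,food_id,common_name,category,rf_pct,n_scats
DHR,summer,Rubus ellipticus,Yeiselu,Buds and twigs,3.2,41
DHR,summer,Arundinaria spp.,Nigalo,Bamboo,34.6,41
DHR,summer,Berberis aristata,Chutro,Buds and twigs,7.9,41
DHR,summer,Lichen,Jhayu,Lichen,5.6,41
DHR,summer,Ants,Ants (Formicidae),Insect,3.3,41
DHR,summer,Paskate (unknown),Paskate,Leaf,3.1,41
DHR,summer,Quercus semicarpifolia (seed),Kharsu seed,Hard mast,5.6,41
DHR,summer,Arisaema tortuosum,Banko seed,Soft mast,11.8,41
DHR,summer,Zea mays,Maize seed,Crop,12.8,41
DHR,summer,Matteuccia struthiopteris,Fern,Fern,10.5,41
DHR,summer,Unidentified,Unidentified,,1.6,41
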