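study_area,season,food_id,common_name,ash_pct,crude_protein_pct,ether_extract_pct,moisture_pct,crude_fiber_pct,available_carbohydrate_pct,source
DHR,autumn,Rubus ellipticus,Yeiselu,9.34,12.17,1.75,12.65,28.17,35.92,composite
DHR,autumn,Arundinaria spp.,Nigalo,9.10,12.44,1.18,12.04,25.06,40.18,literature
DHR,autumn,Berberis aristata,Chutro,5.48,17.86,2.33,9.97,20.13,44.23,literature
DHR,autumn,Lichen,Jhayu,5.72,8.94,1.61,14.06,22.24,47.43,literature
DHR,autumn,Quercus semicarpifolia (leaf),Kharsu leaf,9.97,15.27,3.41,9.21,26.73,35.40,composite
DHR,autumn,Rhododendron spp.,Lali Guransh,10.23,7.82,2.85,12.13,11.72,55.25,composite
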