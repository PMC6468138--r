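study_area,season,food_id,common_name,category,rf_pct,n_scats
KSL,autumn,Berberis aristata,Chutro,Buds and twigs,3.3,59
KSL,autumn,Arundinaria spp.,Nigalo,Bamboo,21.5,59
KSL,autumn,Ficus semicordata,Khanyu seed,Soft mast,7.2,59
KSL,autumn,Ghamari (unknown sp.),Ghamari,Leaf,7.9,59
KSL,autumn,Quercus incana,Banjh,Hard mast,8.6,59
KSL,autumn,Matteuccia struthiopteris,Fern,Fern,15.9,59
KSL,autumn,Rubus ellipticus,Yeiselu,Buds and twigs,7.8,59
KSL,autumn,Rhododendron spp.,Guransh,Leaf,13,59
KSL,autumn,Lichen,Jhayu,Lichen,9.4,59
KSL,autumn,Unidentified,Unidentified,,5.4,59
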