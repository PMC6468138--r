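study_area,season,food_id,common_name,category,rf_pct,n_scats
KSL,summer,Berberis aristata,Chutro,Buds and twigs,2.3,77
KSL,summer,Arundinaria spp.,Nigalo,Bamboo,24.2,77
KSL,summer,Ficus semicordata,Khanyu seed,Soft mast,3.4,77
KSL,summer,Ghamari (unknown sp.),Ghamari,Leaf,5.2,77
KSL,summer,Quercus incana,Banjh,Hard mast,7.1,77
KSL,summer,Matteuccia struthiopteris,Fern,Fern,9.2,77
KSL,summer,Rubus ellipticus,Yeiselu,Buds and twigs,3.4,77
KSL,summer,Arisaema tortuosum,Banko seed,Soft mast,9.5,77
KSL,summer,Paspalum scrobiculatum,Kodo millet,Crop,9.8,77
KSL,summer,Pyrus pyraster,Wild pear seed,Soft mast,13.2,77
KSL,summer,Zea mays,Maize seed,Crop,10.2,77
KSL,summer,Unidentified,Unidentified,,2.5,77
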