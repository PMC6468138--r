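study_area,season,food_id,common_name,ash_pct,crude_protein_pct,ether_extract_pct,moisture_pct,crude_fiber_pct,available_carbohydrate_pct,source
KSL,summer,Berberis aristata,Chutro,3.56,9.21,2.23,8.90,44.33,31.77,composite
KSL,summer,Arundinaria spp.,Nigalo,10.54,8.24,1.40,9.08,45.87,24.87,composite
KSL,summer,Ficus semicordata,Khanyu seed,12.87,6.99,1.45,8.98,24.16,45.55,composite
KSL,summer,Ghamari (unknown sp.),Ghamari,10.84,16.03,6.09,9.95,12.66,44.43,composite
KSL,summer,Quercus incana,Banjh,8.98,9.32,0.37,7.71,38.23,35.40,composite
KSL,summer,Matteuccia struthiopteris,Fern,6.97,8.00,2.09,8.70,36.17,38.07,composite
KSL,summer,Rubus ellipticus,Yeiselu,8.56,10.07,2.31,10.13,25.43,43.50,composite
KSL,summer,Arisaema tortuosum,Banko seed,9.12,11.59,8.90,8.97,9.40,52.01,composite
KSL,summer,Paspalum scrobiculatum,Millet,9.21,7.02,0.18,14.32,35.18,34.08,composite
KSL,summer,Pyrus pyraster,Wild pear seed,12.15,3.69,0.12,10.93,41.34,31.78,composite
KSL,summer,Zea mays,Maize seed,3.65,8.05,2.82,7.90,2.53,75.05,composite
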