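category_name_es,category_name_en,major_type
Bosque de pino (sintetico),Pine forest (synthetic),Coniferous forest
Bosque de oyamel (sintetico),Fir forest (synthetic),Coniferous forest
Bosque de encino (sintetico),Oak forest (synthetic),Highland broadleaf forest
Selva baja caducifolia (sintetico),Lowland deciduous forest (synthetic),Lowland dry forest
Selva mediana subcaducifolia (sintetico),Medium semi-deciduous forest (synthetic),Lowland dry forest
Selva alta perennifolia (sintetico),Tall evergreen forest (synthetic),Lowland evergreen forest
Bosque mesofilo de montana (sintetico),Cloud forest (synthetic),Mountainous cloud forest
Matorral desertico (sintetico),Desert scrub (synthetic),Xerophilous scrub
Matorral crasicaule (sintetico),Succulent scrub (synthetic),Xerophilous scrub
Manglar (sintetico),Mangrove (synthetic),Mangrove and wetland forest
Agricultura de temporal (sintetico),Rain-fed agriculture (synthetic),Other surfaces
Zona urbana (sintetico),Urban area (synthetic),Other surfaces
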