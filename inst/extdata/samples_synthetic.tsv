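sample_id	taxon	hybrid_zone	phenotype_class	role
hyd_pan_1	hydara	panama	postman	ingroup
hyd_pan_2	hydara	panama	postman	ingroup
hyd_pan_3	hydara	panama	postman	ingroup
hyd_pan_4	hydara	panama	postman	ingroup
pet_pan_1	petiverana	panama	postman	ingroup
pet_pan_2	petiverana	panama	postman	ingroup
pet_pan_3	petiverana	panama	postman	ingroup
pet_pan_4	petiverana	panama	postman	ingroup
era_fg_1	erato	french_guiana	rayed	ingroup
era_fg_2	erato	french_guiana	rayed	ingroup
era_fg_3	erato	french_guiana	rayed	ingroup
era_fg_4	erato	french_guiana	rayed	ingroup
era_fg_5	erato	french_guiana	rayed	ingroup
era_fg_6	erato	french_guiana	rayed	ingroup
era_fg_7	erato	french_guiana	rayed	ingroup
hyd_fg_1	hydara	french_guiana	postman	ingroup
hyd_fg_2	hydara	french_guiana	postman	ingroup
hyd_fg_3	hydara	french_guiana	postman	ingroup
hyd_fg_4	hydara	french_guiana	postman	ingroup
hyd_fg_5	hydara	french_guiana	postman	ingroup
hyd_fg_6	hydara	french_guiana	postman	ingroup
emm_per_1	emma	peru	rayed	ingroup
emm_per_2	emma	peru	rayed	ingroup
emm_per_3	emma	peru	rayed	ingroup
emm_per_4	emma	peru	rayed	ingroup
emm_per_5	emma	peru	rayed	ingroup
emm_per_6	emma	peru	rayed	ingroup
emm_per_7	emma	peru	rayed	ingroup
fav_per_1	favorinus	peru	postman	ingroup
fav_per_2	favorinus	peru	postman	ingroup
fav_per_3	favorinus	peru	postman	ingroup
fav_per_4	favorinus	peru	postman	ingroup
fav_per_5	favorinus	peru	postman	ingroup
fav_per_6	favorinus	peru	postman	ingroup
fav_per_7	favorinus	peru	postman	ingroup
lat_ecu_1	lativitta	ecuador	rayed	ingroup
lat_ecu_2	lativitta	ecuador	rayed	ingroup
lat_ecu_3	lativitta	ecuador	rayed	ingroup
lat_ecu_4	lativitta	ecuador	rayed	ingroup
lat_ecu_5	lativitta	ecuador	rayed	ingroup
not_ecu_1	notabilis	ecuador	postman	ingroup
not_ecu_2	notabilis	ecuador	postman	ingroup
not_ecu_3	notabilis	ecuador	postman	ingroup
not_ecu_4	notabilis	ecuador	postman	ingroup
not_ecu_5	notabilis	ecuador	postman	ingroup
him_loj_1	himera	loja	himera	ingroup
him_loj_2	himera	loja	himera	ingroup
him_loj_3	himera	loja	himera	ingroup
him_loj_4	himera	loja	himera	ingroup
him_loj_5	himera	loja	himera	ingroup
cyr_loj_1	cyrbia	loja	postman	ingroup
cyr_loj_2	cyrbia	loja	postman	ingroup
cyr_loj_3	cyrbia	loja	postman	ingroup
cyr_loj_4	cyrbia	loja	postman	ingroup
cly_out_1	clysonymus		outgroup	outgroup
cly_out_2	clysonymus		outgroup	outgroup
tel_out_1	telesiphe		outgroup	outgroup
tel_out_2	telesiphe		outgroup	outgroup
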