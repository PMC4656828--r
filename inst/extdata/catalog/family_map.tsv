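family_id	enzyme_code
ad_abs_1	Abs
ad_bph_1	Bph
ad_bph_2	Bph
ad_bzn_1	Bzn
ad_bzt_1	Bzt
ad_bzt_2	Bzt
ad_cat_1	Cat
ad_cat_2	Cat
ad_2cb_1	2CB
ad_cum_1	Cum
ad_dhb_1	Dhb
ad_dpp_1	Dpp
ad_gen_1	Gen
ad_gen_2	Gen
ad_hna_1	Hna
ad_hpc_1	Hpc
ad_ibu_1	Ibu
ad_ind_1	Ind
ad_odm_1	Odm
ad_orc_1	Orc
ad_pca_1	Pca
ad_pht_1	Pht
ad_thb_1	Thb
ad_rieske_unclassified	nonspecific:rieske_oxygenase
ad_exdo_cupin_unclassified	nonspecific:exdo_cupin
ad_exdo_unclassified	nonspecific:exdo_other
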