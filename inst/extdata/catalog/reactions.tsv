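reaction_id	enzyme_code	substrate	product	step_kind	root_pollutant
rxn_bph	Bph	biphenyl	2,3-dihydroxybiphenyl	multi	biphenyl
rxn_dhb	Dhb	2,3-dihydroxybiphenyl	benzoate	multi	biphenyl
rxn_bzt	Bzt	benzoate	catechol	multi	biphenyl
rxn_cat	Cat	catechol	2-hydroxymuconate semialdehyde	single	biphenyl
rxn_gen	Gen	gentisate	maleylpyruvate	single	gentisate
rxn_ind	Ind	indole-3-acetate	catechol	multi	indole-3-acetate
rxn_odm	Odm	2-oxo-1,2-dihydroquinoline	8-hydroxycoumarin	multi	quinoline
rxn_hna	Hna	1-hydroxy-2-naphthoate	gentisate	multi	phenanthrene
rxn_2cb	2CB	2-chlorobenzoate	catechol	multi	2-chlorobenzoate
rxn_orc	Orc	orcinol	2,3,5-trihydroxytoluene	single	orcinol
rxn_dpp	Dpp	2,3-dihydroxyphenylpropionate	2-hydroxy-6-oxonona-2,4-dienedioate	single	phenylpropionate
rxn_hpc	Hpc	homoprotocatechuate	5-carboxymethyl-2-hydroxymuconate semialdehyde	single	homoprotocatechuate
rxn_bzn	Bzn	benzene	catechol	multi	benzene
rxn_ibu	Ibu	ibuprofen	1,2-dihydroxyibuprofen	multi	ibuprofen
rxn_abs	Abs	4-aminobenzenesulfonate	4-sulfocatechol	single	4-aminobenzenesulfonate
rxn_cum	Cum	p-cumate	2,3-dihydroxy-p-cumate	multi	p-cumate
rxn_thb	Thb	2,2',3-trihydroxybiphenyl	salicylate	single	dibenzofuran
rxn_pht	Pht	phthalate	protocatechuate	multi	phthalate
rxn_pca	Pca	protocatechuate	3-carboxy-cis,cis-muconate	single	phthalate
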