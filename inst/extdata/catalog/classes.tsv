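code	full_name	superfamily	specific
Abs	4-aminobenzenesulfonate 3,4-dioxygenase	rieske_oxygenase	TRUE
Bph	biphenyl dioxygenase	rieske_oxygenase	TRUE
Bzn	benzene dioxygenase	rieske_oxygenase	TRUE
Bzt	benzoate dioxygenase	rieske_oxygenase	TRUE
Cat	catechol 2,3-dioxygenase	exdo_other	TRUE
2CB	2-chlorobenzoate dioxygenase	rieske_oxygenase	TRUE
Cum	p-cumate dioxygenase	rieske_oxygenase	TRUE
Dhb	2,3-dihydroxybiphenyl dioxygenase	exdo_other	TRUE
Dpp	2,3-dihydroxyphenylpropionate dioxygenase	exdo_other	TRUE
Gen	gentisate dioxygenase	exdo_cupin	TRUE
Hna	1-hydroxy-2-naphthoate dioxygenase	exdo_cupin	TRUE
Hpc	homoprotocatechuate 2,3-dioxygenase	exdo_other	TRUE
Ibu	ibuprofen-CoA dioxygenase	other	TRUE
Ind	indole-3-acetate Rieske oxygenase	rieske_oxygenase	TRUE
Odm	2-oxo-1,2-dihydroquinoline monooxygenase	monooxygenase	TRUE
Orc	orcinol hydroxylase	hydroxylase	TRUE
Pca	protocatechuate 3,4-dioxygenase	intradiol_dioxygenase	TRUE
Pht	phthalate 4,5-dioxygenase	rieske_oxygenase	TRUE
Thb	2,2',3-trihydroxybiphenyl dioxygenase	exdo_other	TRUE
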