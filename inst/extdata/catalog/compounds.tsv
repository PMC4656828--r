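canonical_name	synonyms	note
biphenyl		initial pollutant
2,3-dihydroxybiphenyl	dhb	biphenyl ring-dihydroxylation product
benzoate	benzoic acid	central intermediate
catechol	1,2-dihydroxybenzene	central ring-cleavage intermediate
2-hydroxymuconate semialdehyde		catechol meta-cleavage product
gentisate	2,5-dihydroxybenzoate	central ring-cleavage intermediate; also treated as a key pollutant
maleylpyruvate		gentisate ring-cleavage product
indole-3-acetate	indole-3-acetic acid|indoleacetate	plant-auxin-like aromatic acid
2-oxo-1,2-dihydroquinoline	2-oxo-1,2-dihydroxyquinoline	quinoline degradation intermediate
8-hydroxycoumarin		quinoline pathway downstream product
1-hydroxy-2-naphthoate		phenanthrene degradation intermediate
2-chlorobenzoate	2-chlorobenzoic acid	haloaromatic pollutant
orcinol	3,5-dihydroxytoluene	methyl-resorcinol pollutant
2,3,5-trihydroxytoluene		orcinol hydroxylation product
2,3-dihydroxyphenylpropionate		phenylpropionate degradation intermediate
2-hydroxy-6-oxonona-2,4-dienedioate		phenylpropionate ring-cleavage product
homoprotocatechuate	3,4-dihydroxyphenylacetate	central ring-cleavage intermediate
5-carboxymethyl-2-hydroxymuconate semialdehyde		homoprotocatechuate ring-cleavage product
benzene		initial pollutant
ibuprofen	2-(4-isobutylphenyl)propanoate	pharmaceutical pollutant
1,2-dihydroxyibuprofen		ibuprofen dioxygenation product
4-aminobenzenesulfonate	sulfanilate	sulfonated aromatic pollutant
4-sulfocatechol		4-aminobenzenesulfonate dioxygenation product
p-cumate	4-isopropylbenzoate	substituted benzoate pollutant
2,3-dihydroxy-p-cumate		p-cumate dioxygenation product
2,2',3-trihydroxybiphenyl		dibenzofuran degradation intermediate
salicylate	2-hydroxybenzoate	naphthalene/dibenzofuran pathway intermediate
phthalate	benzene-1,2-dicarboxylate	plasticizer pollutant
protocatechuate	3,4-dihydroxybenzoate	central ring-cleavage intermediate
3-carboxy-cis,cis-muconate		protocatechuate ortho-cleavage product
phenylpropionate	3-phenylpropionate	initial pollutant
quinoline		initial pollutant
phenanthrene		initial pollutant
dibenzofuran		initial pollutant
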