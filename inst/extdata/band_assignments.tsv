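label	center	mode	molecule_class
479	479	delta(C-C-C)	carbohydrate
865	865	nu_s(O-C-C-N) C4N+	phospholipid
988	988	delta(C-H3)	chlorophyll
1157	1157	nu(C-C)	carotenoid
1444	1444	sigma(C-H2)	lipid
1524	1524	nu(C=C)	carotenoid
1660	1660	nu(C=C) cis	lipid
1750	1750	nu(C=O)	lipid
2850	2850	nu(C-H2)	lipid
2885	2885	nu(C-H3)	lipid
2940	2940	nu(C-H2)	lipid
2970	2970	nu(C-H3)	lipid
3008	3008	nu_as(=C-H)	lipid
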