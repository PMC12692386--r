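# Click-like reaction template fixtures
# name<TAB>reaction SMARTS<TAB>reagent class
amide_coupling	[C:1](=[O:2])[OH1].[N!H0:3]>>[C:1](=[O:2])[N:3]	amine
ester_formation	[C:1](=[O:2])[OH1].[OH1:3]>>[C:1](=[O:2])[O:3]	alcohol
acid_chloride_acylation	[OH1:1].[C:2](=[O:3])Cl>>[O:1][C:2](=[O:3])	acid_chloride
ether_alkylation	[OH1:1].[C:2]Br>>[O:1][C:2]	bromide
n_alkylation	[N!H0:1].[C:2]Br>>[N:1][C:2]	bromide
urea_formation	[N!H0:1].[N:2]=[C:3]=[O:4]>>[N:1][C:3](=[O:4])[N:2]	isocyanate
sulfonamide_formation	[N!H0:1].[S:2](=[O:3])(=[O:4])Cl>>[N:1][S:2](=[O:3])(=[O:4])	sulfonyl_chloride
azide_alkyne_cycloaddition	[C:1]#[CH1:2].[N:3]=[N+:4]=[N-:5]>>[C:1]1=[C:2][N:3][N+0:4]=[N+0:5]1	azide
reductive_amination	[C!H0:1]=[O].[N!H0:2]>>[C:1][N:2]	amine
epoxide_opening	[C:1]1[C:2][O:3]1.[N!H0:4]>>[N:4][C:1][C:2][O:3]	amine
thiol_ene	[C:1]=[C:2].[S!H0:3]>>[C:1][C:2][S:3]	thiol
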