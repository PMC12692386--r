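# Building-block reagent fixtures: SMILES<TAB>id|class
NCC	bb01|amine
NCCC	bb02|amine
NCCO	bb03|amine
CNC	bb04|amine
NCc1ccccc1	bb05|amine
NC1CCCC1	bb06|amine
OCC	bb07|alcohol
OCCC	bb08|alcohol
OC(C)C	bb09|alcohol
OCc1ccccc1	bb10|alcohol
OCCN	bb11|alcohol
BrCC	bb12|bromide
BrCCC	bb13|bromide
BrCc1ccccc1	bb14|bromide
BrCC=C	bb15|bromide
CCN=[N+]=[N-]	bb16|azide
CCCN=[N+]=[N-]	bb17|azide
OCCN=[N+]=[N-]	bb18|azide
C(c1ccccc1)N=[N+]=[N-]	bb19|azide
CCN=C=O	bb20|isocyanate
CCCN=C=O	bb21|isocyanate
O=C=Nc1ccccc1	bb22|isocyanate
CS(=O)(=O)Cl	bb23|sulfonyl_chloride
CCS(=O)(=O)Cl	bb24|sulfonyl_chloride
c1ccccc1S(=O)(=O)Cl	bb25|sulfonyl_chloride
SCC	bb26|thiol
SCCC	bb27|thiol
SCc1ccccc1	bb28|thiol
CC(=O)Cl	bb29|acid_chloride
CCC(=O)Cl	bb30|acid_chloride
c1ccccc1C(=O)Cl	bb31|acid_chloride
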