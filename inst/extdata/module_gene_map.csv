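gene,ensembl_id,description
LAMC2,ENSG00000058085,laminin subunit gamma 2
COL17A1,ENSG00000065618,collagen type XVII alpha 1 chain
DHRS9,ENSG00000073737,dehydrogenase/reductase 9
SLC2A1,ENSG00000117394,solute carrier family 2 member 1
TNS4,ENSG00000131746,tensin 4
SCEL,ENSG00000136155,sciellin
TMPRSS4,ENSG00000137648,transmembrane serine protease 4
MAL2,ENSG00000147676,"mal, T cell differentiation protein 2"
SPRR3,ENSG00000163209,small proline rich protein 3
SPINT2,ENSG00000167642,"serine peptidase inhibitor, Kunitz type 2"
KRT19,ENSG00000171345,keratin 19
CST6,ENSG00000175315,cystatin E/M
LEMD1,ENSG00000186007,LEM domain containing 1
S100A14,ENSG00000189334,S100 calcium binding protein A14
S100A2,ENSG00000196754,S100 calcium binding protein A2
LAMB3,ENSG00000196878,laminin subunit beta 3
KRT6A,ENSG00000205420,keratin 6A
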