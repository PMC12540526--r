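abbrev,full_name,role,msa_group,nester_abundance,region
NUSA,Northern US Limit (South Carolina; North Carolina; Delaware),rookery,USA,,North Atlantic
CEFL,Central eastern Florida,rookery,USA,,North Atlantic
SEFL,Southeastern Florida,rookery,USA,,North Atlantic
MKFL,Key West Florida,rookery,USA,,North Atlantic
DTFL,Dry Tortugas Florida,rookery,USA,,North Atlantic
QRMX,Quintana Roo Mexico,rookery,MX,,North Atlantic
WBCMX,Tamaulipas and Veracruz Mexico,rookery,MX,,North Atlantic
EBCMX,Campeche and Yucatan Mexico,rookery,MX,,North Atlantic
CAMX,Cayo Arcas Campeche Mexico,rookery,MX,,North Atlantic
SRMX,Scorpion Reef Yucatan Mexico,rookery,MX,,North Atlantic
GUCB,Guanahacabibes Peninsula and San Felipe Cuba,rookery,CUB,,North Atlantic
IJCB,Isla de la Juventud Cuba,rookery,CUB,,North Atlantic
CLCB,Cayo Largo Cuba,rookery,CUB,,North Atlantic
CR,Tortuguero Costa Rica,rookery,CR,,North Atlantic
CI,Grand Cayman (wild population) Cayman Islands,rookery,CI,,North Atlantic
BUC,Buck Island,rookery,BUC,,North Atlantic
AV,Aves Island Venezuela,rookery,AV,,North Atlantic
SUR,Matapica and Galibi Suriname,rookery,SUR,,North Atlantic
FG,Cayenne French Guiana,rookery,FG,,North Atlantic
RA,Atol das Rocas Brazil,rookery,RA,,South Atlantic
FN,Fernando de Noronha Brazil,rookery,FN,,South Atlantic
TRI,Trindade Island Brazil,rookery,TRI,,South Atlantic
ASC,Ascension Island UK,rookery,ASC,14840,South Atlantic
GB,Poilao Guinea-Bissau,rookery,GB,,South Atlantic
STP,Sao Tome and Principe,rookery,STP,,South Atlantic
ALG,Alagoas Brazil,foraging,,,South Atlantic
CorV,Coroa Vermelha Brazil,foraging,,,South Atlantic
ARA,Aracruz Brazil,foraging,,,South Atlantic
URU,Uruguay,foraging,,,South Atlantic
CON,Congo,foraging,,,South Atlantic
STP_F,Sao Tome and Principe (foraging),foraging,,,South Atlantic
UNH,Unhocomo Guinea-Bissau,foraging,,,South Atlantic
BA,Parc National du Banc D'Arguin Mauritania,foraging,,,South Atlantic
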