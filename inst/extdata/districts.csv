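code,name,province,region,coastal
AVR,Aveiro,Beira Litoral,Centro,Yes
BJA,Beja,Baixo Alentejo,Alentejo,Yes
BRG,Braga,Minho,Norte,Yes
BGC,Braganca,Tras-os-Montes,Norte,No
CTB,Castelo Branco,Beira Baixa,Centro,No
CBR,Coimbra,Beira Litoral,Centro,Yes
EVR,Evora,Alto Alentejo,Alentejo,No
FAR,Faro,Algarve,Algarve,Yes
GRD,Guarda,Beira Alta,Centro,No
LRA,Leiria,Estremadura,Centro,Yes
LSB,Lisboa,Estremadura,Lisboa,Yes
PTG,Portalegre,Alto Alentejo,Alentejo,No
PRT,Porto,Douro Litoral,Norte,Yes
STR,Santarem,Ribatejo,Alentejo,No
STB,Setubal,Estremadura,Lisboa,Yes
VCT,Viana do Castelo,Minho,Norte,Yes
VRL,Vila Real,Tras-os-Montes,Norte,No
VIS,Viseu,Beira Alta,Centro,No
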