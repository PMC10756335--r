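drug_id,smiles
aspirin,CC(=O)OC1=CC=CC=C1C(=O)O
caffeine,CN1C=NC2=C1C(=O)N(C(=O)N2C)C
paracetamol,CC(=O)NC1=CC=C(C=C1)O
ibuprofen,CC(C)CC1=CC=C(C=C1)C(C)C(=O)O
naproxen,CC(C1=CC2=CC(=CC=C2C=C1)OC)C(=O)O
gefitinib,COC1=C(C=C2C(=C1)N=CN=C2NC3=CC(=C(C=C3)F)Cl)OCCCN4CCOCC4
erlotinib,COCCOC1=C(C=C2C(=C1)C(=NC=N2)NC3=CC=CC(=C3)C#C)OCCOC
imatinib,CC1=C(C=C(C=C1)NC(=O)C2=CC=C(C=C2)CN3CCN(CC3)C)NC4=NC=CC(=N4)C5=CC=CN=C5
sorafenib,CNC(=O)C1=NC=CC(=C1)OC2=CC=C(C=C2)NC(=O)NC3=CC(=C(C=C3)Cl)C(F)(F)F
sunitinib,CCN(CC)CCNC(=O)C1=C(NC(=C1C)C=C2C3=C(C=CC(=C3)F)NC2=O)C
lapatinib,CS(=O)(=O)CCNCC1=CC=C(O1)C2=CC3=C(C=C2)N=CN=C3NC4=CC(=C(C=C4)OCC5=CC(=CC=C5)F)Cl
dasatinib,CC1=C(C(=CC=C1)Cl)NC(=O)C2=CN=C(S2)NC3=CC(=NC(=N3)C)N4CCN(CC4)CCO
nilotinib,CC1=CN(C=N1)C2=CC(=CC(=C2)C(F)(F)F)NC(=O)C3=CC=C(C(=C3)NC4=NC=CC(=N4)C5=CC=CN=C5)C
paclitaxel,CC1=C2C(C(=O)C3(C(CC4C(C3C(C(C2(C)C)(CC1OC(=O)C(C(C5=CC=CC=C5)NC(=O)C6=CC=CC=C6)O)O)OC(=O)C7=CC=CC=C7)(CO4)OC(=O)C)O)C)OC(=O)C
docetaxel,CC1=C2C(C(=O)C3(C(CC4C(C3C(C(C2(C)C)(CC1O)O)OC(=O)C5=CC=CC=C5)(CO4)OC(=O)C)O)C)OC(=O)C(C(C6=CC=CC=C6)NC(=O)OC(C)(C)C)O
doxorubicin,CC1C(C(CC(O1)OC2CC(CC3=C2C(=C4C(=C3O)C(=O)C5=C(C4=O)C(=CC=C5)OC)O)(C(=O)CO)O)N)O
etoposide,CC1OCC2C(O1)C(C(C(O2)OC3C4COC(=O)C4C(C5=CC6=C(C=C35)OCO6)C7=CC(=C(C(=C7)OC)O)OC)O)O
5-fluorouracil,C1=C(C(=O)NC(=O)N1)F
gemcitabine,C1=CN(C(=O)N=C1N)C2C(C(C(O2)CO)O)(F)F
methotrexate,CN(CC1=CN=C2C(=N1)C(=NC(=N2)N)N)C3=CC=C(C=C3)C(=O)NC(CCC(=O)O)C(=O)O
cisplatin-ligand,NCCN
temozolomide,CC1=NN2C=C(C(=O)N(C2=N1)C)C(=O)N
vinblastine-core,C1CCC2=CC=CC=C2C1
tamoxifen,CCC(=C(C1=CC=CC=C1)C2=CC=C(C=C2)OCCN(C)C)C3=CC=CC=C3
fulvestrant-core,CC12CCC3C(C1CCC2O)CCC4=C3C=CC(=C4)O
letrozole,C1=CC(=CC=C1C(C2=CC=C(C=C2)C#N)N3C=NC=N3)C#N
anastrozole,CC(C)(C#N)C1=CC(=CC(=C1)CN2C=NC=N2)C(C)(C)C#N
bicalutamide,CC(CS(=O)(=O)C1=CC=C(C=C1)F)(C(=O)NC2=CC(=C(C=C2)C#N)C(F)(F)F)O
enzalutamide,CC1(C(=O)N(C(=S)N1C2=CC(=C(C=C2)C#N)C(F)(F)F)C3=CC(=C(C=C3)C(=O)NC)F)C
olaparib,C1CC1C(=O)N2CCN(CC2)C(=O)C3=C(C=CC=C3F)CC4=NNC(=O)C5=CC=CC=C45
vemurafenib,CCCS(=O)(=O)NC1=C(C(=C(C=C1)F)C(=O)C2=CNC3=NC=C(C=C23)C4=CC=C(C=C4)Cl)F
dabrafenib,CC(C)(C)C1=NC(=C(S1)C2=NC(=NC=C2)N)C3=C(C(=CC=C3)NS(=O)(=O)C4=C(C=CC=C4F)F)F
trametinib-core,CN1C(=O)C=CC1=O
crizotinib,CC(C1=C(C=CC(=C1Cl)F)Cl)OC2=C(N=CC(=C2)C3=CN(N=C3)C4CCNCC4)N
bortezomib,CC(C)CC(NC(=O)C(CC1=CC=CC=C1)NC(=O)C2=NC=CN=C2)B(O)O
carfilzomib-frag,CC(C)CC(C(=O)NC(CC1=CC=CC=C1)C(=O)N)N
vorinostat,C1=CC=C(C=C1)NC(=O)CCCCCCC(=O)NO
romidepsin-frag,CC(C)C1NC(=O)C(C)NC(=O)C(=CC)NC1=O
topotecan,CCC1(C2=C(COC1=O)C(=O)N3CC4=CC5=C(C=CC(=C5CN(C)C)O)N=C4C3=C2)O
irinotecan-core,CCC1=CC2=CC=CC=C2N=C1
mitoxantrone,C1=CC2=C(C(=C1)O)C(=O)C3=C(C2=O)C(=CC=C3NCCNCCO)NCCNCCO
bleomycin-frag,NC(=O)CC(N)C(=O)N
dactinomycin-frag,CC1=CC=CC=C1N
carmustine,C(CCl)N(CCCl)C(=O)N
lomustine,C1CCC(CC1)NC(=O)N(CCCl)N=O
busulfan,CS(=O)(=O)OCCCCOS(=O)(=O)C
chlorambucil,C1=CC(=CC=C1CCCC(=O)O)N(CCCl)CCCl
melphalan,C1=CC(=CC=C1CC(C(=O)O)N)N(CCCl)CCCl
cyclophosphamide,C1CNP(=O)(OC1)N(CCCl)CCCl
ifosfamide,C1CN(P(=O)(OC1)NCCCl)CCCl
dacarbazine,CN(C)N=NC1=C(NC=N1)C(=O)N
procarbazine,CC(C)NC(=O)C1=CC=C(C=C1)CNNC
hydroxyurea,C(=O)(N)NO
azacitidine,C1=NC(=NC(=O)N1C2C(C(C(O2)CO)O)O)N
decitabine,C1C(C(OC1N2C=NC(=NC2=O)N)CO)O
cladribine,C1C(C(OC1N2C=NC3=C(N=C(N=C32)Cl)N)CO)O
fludarabine,C1=NC2=C(N=C(N=C2N1C3C(C(C(O3)CO)O)O)F)N
pemetrexed,CC1=C(C=C(C=C1)C(=O)NC(CCC(=O)O)C(=O)O)CCC2=CNC3=C2C(=O)NC(=N3)N
capecitabine,CCCCCOC(=O)NC1=NC(=O)N(C=C1F)C2C(C(C(O2)C)O)O
cytarabine,C1=CN(C(=O)N=C1N)C2C(C(C(O2)CO)O)O
mercaptopurine,C1=NC2=C(N1)C(=S)N=CN2
thioguanine,C1=NC2=C(N1)C(=S)N=C(N2)N
allopurinol,C1=NNC2=C1C(=O)N=CN2
axitinib,CNC(=O)C1=CC=CC=C1SC2=CC3=C(C=C2)C(=NN3)C=CC4=CC=CC=N4
pazopanib,CC1=C(C=C(C=C1)NC2=NC=CC(=N2)N(C)C3=CC4=NN(C(=C4C=C3)C)C)S(=O)(=O)N
regorafenib,CNC(=O)C1=NC=CC(=C1)OC2=CC(=C(C=C2)NC(=O)NC3=CC(=C(C=C3)Cl)C(F)(F)F)F
ponatinib,CC1=C(C=C(C=C1)C(=O)NC2=CC(=C(C=C2)CN3CCN(CC3)C)C(F)(F)F)C#CC4=CN=C5N4N=CC=C5
ruxolitinib,C1CCC(C1)C(CC#N)N2C=C(C=N2)C3=C4C=CNC4=NC=N3
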