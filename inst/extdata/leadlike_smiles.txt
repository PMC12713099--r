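# Synthetic sample of lead-like SMILES used to derive the default 39-token
# character vocabulary (frequency-ranked, ties lexicographic). Assembled by
# hand to cover the token inventory of drug-like chemistry; not real
# screening data.
CC(=O)Oc1ccccc1C(=O)O
CC(C)Cc1ccc(cc1)C(C)C(=O)O
CN1CCC[C@H]1c1cccnc1
Clc1ccccc1C(=O)NCCN1CCOCC1
Brc1ccc(cc1)S(=O)(=O)N1CCNCC1
Fc1ccc(cc1)C(=O)Nc1ccccn1
Ic1ccc(cc1)C#N
OC[C@@H](N)Cc1c[nH]cn1
N[C@@H](Cc1ccc(O)cc1)C(=O)O
CC(C)(C)OC(=O)N1CCC(CC1)N
O=C(Nc1ccccc1)c1ccco1
O=C(Nc1ccccc1)c1cccs1
c1ccc2c(c1)cccn2
c1ccc2c(c1)[nH]cn2
CCOC(=O)c1cnc2ccccc2c1
CN(C)CCOc1ccc(cc1)C(=O)c1ccccc1
CC1=CC(=O)C=CC1=O
COc1cc2c(cc1OC)CCN(C)C2
NS(=O)(=O)c1ccc(Cl)cc1
OC(=O)c1cc(ccc1O)[N+](=O)[O-]
C[N+](C)(C)CC([O-])=O
NC(=N)c1ccc(cc1)Oc1ccccc1
CC(=O)Nc1nnc(s1)S(N)(=O)=O
O=C1CCCCCN1
C1CCOC1
C1CCNCC1
C1CCSCC1
O=S(=O)(c1ccccc1)N1CCCC1
CC/C=C/CO
C/C=C\C(=O)O
OCC#CCO
CC(C)=CCCC(C)=CC=O
COC(=O)C1=C(C)NC(C)=C(C1c1ccccc1[N+]([O-])=O)C(=O)OC
CCN(CC)CCNC(=O)c1ccc(N)cc1
Cn1cnc2c1c(=O)n(C)c(=O)n2C
OC1CC2CCC1(C)C2(C)C
CC34CCC1C(CCc2cc(O)ccc12)C3CCC4=O
CC(=O)OCC1=C(N2C(=O)C(NC(=O)Cc3ccccc3)C2SC1)C(=O)O
N#Cc1ccc(cc1)N1CCN(CC1)c1ncnc2[nH]cnc12
CC(C)n1cnc2c(N)ncnc12
O=c1[nH]c(=O)n(c(=O)[nH]1)C1CC1
CCCCCCCCCC(=O)OCC
c1ccc(cc1)P(c1ccccc1)c1ccccc1
O=[N+]([O-])c1ccc2ncccc2c1
Clc1ccc2OCOc2c1
FC(F)(F)c1ccc(cc1)C1CCNCC1
BrCC(=O)N1CCc2ccccc12
C[Se]c1ccccc1
CC(C)[C@@H](C(=O)O)N
CC[C@H](C)[C@H](N)C(=O)O
OC(=O)CC%10(CC(=O)O)CCCC%10
C1CC2CCC1CC2
COc1ccc(cc1)/C=C/C(=O)c1ccc(O)cc1
B(O)(O)c1ccccc1
CC(C)(C)c1ccc(O)cc1
C12C3C4C1C5C2C3C45
C1CC1C2CC2C3CC3C4CC4C5CC5C6CC6C7CC7C8CC8C9CC9
c1:c:c:c:c:c1
CC(=O)[O-].[NH4+]
CN(C)C(=O)C1CCC(CC1)N2CCOCC2
Oc1ccc2[nH]c3CCN(C)Cc3c2c1
O=C(OCC)C=Cc1ccccc1
N#CC1(CCN(CC1)Cc1ccccc1)c1ccccc1
CNC(=O)c1cc(Oc2ccc(NC(=O)Nc3ccc(Cl)c(c3)C(F)(F)F)cc2)ccn1
CC1(C)SC2C(NC(=O)Cc3ccccc3)C(=O)N2C1C(=O)O
OCC(O)C(O)C(O)C(O)CO
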