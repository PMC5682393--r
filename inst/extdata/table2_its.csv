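population,species,n,haplotypes
A,N. incisum,13,H1:13
B,N. incisum,5,H1:5
C,N. incisum,10,H1:10
D,N. incisum,10,H2:10
E,N. incisum,5,H1:1;H3:1;H4:1;H5:2
F,N. incisum,10,H1:10
G,N. incisum,12,H6:2;H7:7;H8:3
H,N. incisum,10,H4:2;H9:1;H10:5;H11:2
I,N. incisum,10,H1:10
J,N. incisum,10,H4:1;H6:2;H7:3;H8:1;H12:2;H13:1
L,N. incisum,10,H7:10
M,N. incisum,10,H1:10
N,N. incisum,10,H7:10
Q,N. incisum,10,H7:9;H14:1
S,N. incisum,10,H7:10
T,N. incisum,5,H1:5
U,N. incisum,6,H1:1;H7:2;H15:2;H16:1
V,N. incisum,6,H7:4;H17:1;H18:1
W,N. incisum,6,H1:3;H7:2;H16:1
X,N. incisum,8,H7:4;H16:1;H19:1;H20:1;H21:1
Y,N. incisum,2,H7:2
Z,N. incisum,5,H1:5
HA,N. incisum,5,H1:5
HB,N. incisum,5,H1:3;H7:1;H16:1
HC,N. incisum,5,H1:1;H7:3;H16:1
HF,N. incisum,5,H2:5
HH,N. incisum,6,H7:5;H16:1
HI,N. incisum,5,H1:5
KA,N. franchetii,9,H22:9
KC,N. franchetii,10,H22:10
KD,N. franchetii,10,H22:10
KE,N. franchetii,2,H23:2
KF,N. franchetii,7,H22:7
KG,N. franchetii,10,H24:4;H25:1;H26:5
KH,N. franchetii,10,H22:10
KI,N. franchetii,9,H22:6;H27:1;H28:1;H29:1
KJ,N. franchetii,10,H22:4;H30:2;H31:1;H32:3
KK,N. franchetii,10,H22:1;H30:1;H32:2;H33:6
KL,N. franchetii,10,H22:10
KM,N. franchetii,10,H23:10
KN,N. franchetii,2,H23:2
KO,N. franchetii,5,H22:5
KP,N. franchetii,5,H22:3;H32:1;H34:1
KQ,N. franchetii,10,H22:10
KR,N. franchetii,2,H22:2
KS,N. franchetii,5,H22:5
KV,N. franchetii,6,H22:6
KX,N. franchetii,6,H22:6
KZ,N. franchetii,6,H22:5;H35:1
YA,N. franchetii,5,H22:5
YB,N. franchetii,5,H22:5
YC,N. franchetii,9,H36:5;H37:3;H38:1
YD,N. franchetii,5,H36:3;H37:1;H39:1
YE,N. franchetii,6,H22:4;H40:1;H41:1
YF,N. franchetii,6,H36:1;H37:1;H42:4
YK,N. franchetii,5,H22:5
YM,N. franchetii,5,H22:5
LA,N. oviforme,10,H43:1;H44:9
LB,N. oviforme,10,H45:10
LC,N. oviforme,10,H44:1;H45:9
LD,N. oviforme,17,H46:17
LE,N. oviforme,15,H46:15
LF,N. oviforme,10,H47:10
LG,N. oviforme,2,H44:2
LK,N. oviforme,5,H46:5
LO,N. oviforme,5,H46:5
LP,N. oviforme,5,H44:5
LQ,N. oviforme,5,H46:5
LT,N. oviforme,5,H44:1;H45:4
LU,N. oviforme,6,H44:1;H45:5
LCA,N. forrestii,10,H48:10
LCB,N. forrestii,10,H48:10
LCC,N. forrestii,10,H48:10
LCD,N. forrestii,10,H48:10
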