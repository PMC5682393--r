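population,species,n,haplotypes
A,N. incisum,13,H1:13
B,N. incisum,5,H1:5
C,N. incisum,10,H1:10
D,N. incisum,10,H2:8;H3:2
E,N. incisum,5,H3:5
F,N. incisum,10,H3:10
G,N. incisum,12,H4:5;H5:7
H,N. incisum,10,H6:10
I,N. incisum,10,H1:10
J,N. incisum,10,H3:2;H5:4;H7:2;H8:2
L,N. incisum,10,H3:9;H7:1
M,N. incisum,10,H9:4;H10:6
N,N. incisum,10,H11:1;H12:9
Q,N. incisum,10,H3:5;H12:1;H13:1;H14:1;H15:1;H16:1
S,N. incisum,10,H17:10
T,N. incisum,5,H3:5
U,N. incisum,5,H6:2;H18:2;H19:1
V,N. incisum,5,H6:5
W,N. incisum,5,H3:1;H4:3;H18:1
X,N. incisum,5,H3:3;H18:1;H20:1
Y,N. incisum,2,H6:2
Z,N. incisum,5,H3:1;H21:1;H22:1;H23:2
HA,N. incisum,5,H24:4;H25:1
HB,N. incisum,5,H26:1;H27:2;H28:2
HC,N. incisum,5,H26:1;H29:2;H30:1;H31:1
HF,N. incisum,5,H2:5
HH,N. incisum,6,H6:5;H26:1
HI,N. incisum,5,H24:5
KA,N. franchetii,9,H32:9
KC,N. franchetii,10,H32:8;H33:2
KD,N. franchetii,10,H33:10
KE,N. franchetii,2,H34:2
KF,N. franchetii,7,H33:7
KG,N. franchetii,10,H32:1;H35:8;H36:1
KH,N. franchetii,10,H33:10
KI,N. franchetii,9,H32:9
KJ,N. franchetii,10,H32:10
KK,N. franchetii,10,H32:10
KL,N. franchetii,10,H33:10
KM,N. franchetii,10,H34:10
KN,N. franchetii,2,H34:2
KO,N. franchetii,5,H32:3;H36:2
KP,N. franchetii,5,H32:5
KQ,N. franchetii,10,H32:8;H33:2
KR,N. franchetii,2,H37:2
KS,N. franchetii,5,H33:5
KV,N. franchetii,6,H33:6
KX,N. franchetii,6,H33:6
KZ,N. franchetii,6,H33:3;H38:3
YA,N. franchetii,5,H32:5
YB,N. franchetii,5,H33:5
YC,N. franchetii,5,H39:5
YD,N. franchetii,5,H32:5
YE,N. franchetii,5,H32:4;H33:1
YF,N. franchetii,5,H39:4;H40:1
YK,N. franchetii,5,H33:5
YM,N. franchetii,5,H32:1;H33:4
LA,N. oviforme,10,H41:10
LB,N. oviforme,10,H42:10
LC,N. oviforme,10,H43:7;H44:3
LD,N. oviforme,17,H45:17
LE,N. oviforme,15,H41:1;H46:9;H47:5
LF,N. oviforme,10,H32:10
LG,N. oviforme,2,H44:2
LK,N. oviforme,5,H48:5
LO,N. oviforme,5,H49:5
LP,N. oviforme,5,H50:2;H51:3
LQ,N. oviforme,5,H41:5
LT,N. oviforme,5,H42:1;H51:4
LU,N. oviforme,5,H52:5
LCA,N. forrestii,10,H53:7;H54:3
LCB,N. forrestii,10,H55:10
LCC,N. forrestii,10,H53:10
LCD,N. forrestii,10,H53:9;H54:1
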