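CCN1C=C(C(=O)O)C(=O)c2ccc(C)nc21	Nalidixic acid
CCN1C=C(C(=O)O)C(=O)c2cc3c(cc21)OCO3	Oxolinic Acid
CCN1N=C(C(=O)O)C(=O)c2cc3c(cc21)OCO3	Cinoxacin
CCN1C=C(C(=O)O)C(=O)c2ccc(-c3ccncc3)cc21	Rosoxacin
CCN1C=C(C(=O)O)C(=O)c2cc(F)c(N3CCNCC3)cc21	Norfloxacin
CCN1C=C(C(=O)O)C(=O)c2cc(F)c(N3CCNCC3)nc21	Enoxacin
OC(=O)C1=CN(C2CC2)c2cc(N3CCNCC3)c(F)cc2C1=O	Ciprofloxacin
CCN1CCN(c2cc3c(cc2F)C(=O)C(C(=O)O)=CN3C2CC2)CC1	Enrofloxacin
CN1CCN(c2cc3c(cc2F)C(=O)C(C(=O)O)=CN3c2ccc(F)cc2)CC1	Difloxacin
CC1CN(c2cc3c(cc2F)C(=O)C(C(=O)O)=CN3c2ccc(F)cc2F)CCN1	Temafloxacin
CC1COc2c(N3CCN(C)CC3)c(F)cc3c2N1C=C(C(=O)O)C3=O	Ofloxacin
C[C@H]1COc2c(N3CCN(C)CC3)c(F)cc3c2N1C=C(C(=O)O)C3=O	Levofloxacin
CN1CCN(c2c(F)cc3C(=O)C(C(=O)O)=CN4CCSc(c34)2)CC1	Rufloxacin
CN1CCN(c2c(F)cc3c(c2F)N(CCF)C=C(C(=O)O)C3=O)CC1	Fleroxacin
CC1CN(c2c(F)c(N)c3c(c2F)N(C2CC2)C=C(C(=O)O)C3=O)CC(C)N1	Sparfloxacin
OC(=O)C1=CN(c2ccc(F)cc2F)c3nc(N4CC5C(N)C5C4)c(F)cc3C1=O	Trovafloxacin
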