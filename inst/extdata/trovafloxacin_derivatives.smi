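OC(=O)C1=CN(c2ccc(F)cc2F)c3nc(N4CC5C([N+](=O)[O-])C5C4)c(F)cc3C1=O	Derivative-1
OC(=O)C1=CN(c2ccc(F)cc2F)c3nc(N4CC5C(CC)C5C4)c(F)cc3C1=O	Derivative-2
OC(=O)C1=CN(c2ccc(F)cc2F)c3nc(N4CC5C(CCC)C5C4)c(F)cc3C1=O	Derivative-3
OC(=O)C1=CN(c2ccc(F)cc2F)c3nc(N4CC5C(N)C5C4)c(F)c([SiH3])c3C1=O	Derivative-4
OC(=O)C1=CN(c2ccc(F)cc2F)c3nc(N4CC5C(N)C5C4)c(F)c(P)c3C1=O	Derivative-5
OC(=O)C1=CN(c2ccc(F)cc2F)c3nc(N4CC5C([N+](=O)[O-])C5C4)c(F)c([SiH3])c3C1=O	Derivative-6
OC(=O)C1=CN(c2ccc(F)cc2F)c3nc(N4CC5C(OC)C5C4)c(F)c([SiH3])c3C1=O	Derivative-7
OC(=O)C1=CN(c2ccc(F)cc2F)c3nc(N4CC5C(OC)C5C4)c(F)c(P)c3C1=O	Derivative-8
OC(=O)C1=CN(c2ccc(F)cc2F)c3nc(N4CC5C(S)C5C4)c(F)c(P)c3C1=O	Derivative-9
OC(=O)C1=CN(c2ccc(F)cc2F)c3nc(N4CC5C(CC)C5C4)c(F)c(P)c3C1=O	Derivative-10
OC(=O)C1=CN(c2ccc(F)cc2F)c3nc(N4CC5C(CCC)C5C4)c(F)c(P)c3C1=O	Derivative-11
OC(=O)C1=CN(c2ccc(F)cc2F)c3nc(N4CC5CC5C4)c(F)cc3C1=O	Derivative-12
OC(=O)C1=CN(c2ccc(F)cc2F)c3nc(N4CC5C(C)C5C4)c(F)cc3C1=O	Derivative-13
OC(=O)C1=CN(c2ccc(F)cc2F)c3nc(N4CC5C(C=C)C5C4)c(F)cc3C1=O	Derivative-14
OC(=O)C1=CN(c2ccc(F)cc2F)c3nc(N4CC5C(OC)C5C4)c(F)cc3C1=O	Derivative-15
OC(=O)C1=CN(c2ccc(F)cc2F)c3nc(N4CC5C(S)C5C4)c(F)cc3C1=O	Derivative-16
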