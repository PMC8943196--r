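name_a	smiles_a	name_b	smiles_b
NAD+	NC(=O)c1ccc[n+](c1)C1OC(COP(=O)(O)OP(=O)(O)OCC2OC(n3cnc4c(N)ncnc43)C(O)C2O)C(O)C1O	NADH	NC(=O)C1=CN(C=CC1)C1OC(COP(=O)(O)OP(=O)(O)OCC2OC(n3cnc4c(N)ncnc43)C(O)C2O)C(O)C1O
NADP+	NC(=O)c1ccc[n+](c1)C1OC(COP(=O)(O)OP(=O)(O)OCC2OC(n3cnc4c(N)ncnc43)C(OP(=O)(O)O)C2O)C(O)C1O	NADPH	NC(=O)C1=CN(C=CC1)C1OC(COP(=O)(O)OP(=O)(O)OCC2OC(n3cnc4c(N)ncnc43)C(OP(=O)(O)O)C2O)C(O)C1O
ATP	Nc1ncnc2n(cnc12)C1OC(COP(=O)(O)OP(=O)(O)OP(=O)(O)O)C(O)C1O	ADP	Nc1ncnc2n(cnc12)C1OC(COP(=O)(O)OP(=O)(O)O)C(O)C1O
ATP	Nc1ncnc2n(cnc12)C1OC(COP(=O)(O)OP(=O)(O)OP(=O)(O)O)C(O)C1O	AMP	Nc1ncnc2n(cnc12)C1OC(COP(=O)(O)O)C(O)C1O
ADP	Nc1ncnc2n(cnc12)C1OC(COP(=O)(O)OP(=O)(O)O)C(O)C1O	AMP	Nc1ncnc2n(cnc12)C1OC(COP(=O)(O)O)C(O)C1O
CoA	CC(C)(COP(=O)(O)OP(=O)(O)OCC1OC(n2cnc3c(N)ncnc32)C(OP(=O)(O)O)C1O)C(O)C(=O)NCCC(=O)NCCS	acetyl-CoA	CC(=O)SCCNC(=O)CCNC(=O)C(O)C(C)(C)COP(=O)(O)OP(=O)(O)OCC1OC(n2cnc3c(N)ncnc32)C(OP(=O)(O)O)C1O
glutamate	NC(CCC(=O)O)C(=O)O	2-oxoglutarate	O=C(CCC(=O)O)C(=O)O
alanine	CC(N)C(=O)O	pyruvate	CC(=O)C(=O)O
dioxygen	O=O	hydrogen peroxide	OO
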