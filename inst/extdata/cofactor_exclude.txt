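# Common currency metabolites excluded from reference-pathway linearization
# graphs (one SMILES per line, '#' comments allowed). Editable.
NC(=O)c1ccc[n+](c1)C1OC(COP(=O)(O)OP(=O)(O)OCC2OC(n3cnc4c(N)ncnc43)C(O)C2O)C(O)C1O	NAD+
NC(=O)C1=CN(C=CC1)C1OC(COP(=O)(O)OP(=O)(O)OCC2OC(n3cnc4c(N)ncnc43)C(O)C2O)C(O)C1O	NADH
NC(=O)c1ccc[n+](c1)C1OC(COP(=O)(O)OP(=O)(O)OCC2OC(n3cnc4c(N)ncnc43)C(OP(=O)(O)O)C2O)C(O)C1O	NADP+
NC(=O)C1=CN(C=CC1)C1OC(COP(=O)(O)OP(=O)(O)OCC2OC(n3cnc4c(N)ncnc43)C(OP(=O)(O)O)C2O)C(O)C1O	NADPH
Nc1ncnc2n(cnc12)C1OC(COP(=O)(O)OP(=O)(O)OP(=O)(O)O)C(O)C1O	ATP
Nc1ncnc2n(cnc12)C1OC(COP(=O)(O)OP(=O)(O)O)C(O)C1O	ADP
Nc1ncnc2n(cnc12)C1OC(COP(=O)(O)O)C(O)C1O	AMP
O	water
O=O	dioxygen
OO	hydrogen peroxide
O=C=O	carbon dioxide
N	ammonia
OP(=O)(O)O	phosphate
OP(=O)(O)OP(=O)(O)O	diphosphate
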