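# Toy generalized reaction-rule library.
#
# Eight bidirectional rules spanning oxidoreductase, transferase, hydrolase
# and lyase chemistry. Each rule lists its pattern atoms
# (ATOM <index> <element> <charge> <min_h> <source-fragment> <product-fragment>),
# the site bond-electron matrix (diagonal '.' = non-bonding electrons
# unconstrained), the difference matrix, the per-atom hydrogen change, and
# the fixed co-substrate / co-product templates as SMILES.
#
# The redox carrier pair is dioxygen / hydrogen peroxide (oxidase-style
# chemistry), the methyl donor is methanol, and the amino donor pair is
# 2-aminopropanoate / pyruvate.

RULE r1_alcohol_oxidase
EC 1.1.3
NAME alcohol oxidation to carbonyl (O2 -> H2O2)
ATOM 1 C 0 1 S P
ATOM 2 O 0 1 S P
ATOM 3 O 0 0 C1 Q1
ATOM 4 O 0 0 C1 Q1
SITE
. 1 0 0
1 . 0 0
0 0 . 2
0 0 2 .
DELTA
0 1 0 0
1 0 0 0
0 0 0 -1
0 0 -1 0
HDELTA -1 -1 1 1
COSUB C1 O=O
COPROD Q1 OO
END

RULE r2_aldehyde_oxidase
EC 1.2.3
NAME aldehyde oxidation to carboxylic acid (H2O2 -> H2O)
ATOM 1 C 0 1 S P
ATOM 2 O 0 0 S P
ATOM 3 O 0 1 C1 P
ATOM 4 O 0 1 C1 Q1
SITE
. 2 0 0
2 . 0 0
0 0 . 1
0 0 1 .
DELTA
0 0 1 0
0 0 0 0
1 0 0 -1
0 0 -1 0
HDELTA -1 0 0 1
COSUB C1 OO
COPROD Q1 O
END

RULE r3_o_methyltransferase
EC 2.1.1
NAME hydroxyl O-methylation (methanol donor)
ATOM 1 O 0 1 S P
ATOM 2 C 0 3 C1 P
ATOM 3 O 0 1 C1 Q1
SITE
. 0 0
0 . 1
0 1 .
DELTA
0 1 0
1 0 -1
0 -1 0
HDELTA -1 0 1
COSUB C1 CO
COPROD Q1 O
END

RULE r4_transaminase
EC 2.6.1
NAME amino transfer from 2-aminopropanoate to a carbonyl
ATOM 1 C 0 0 S P
ATOM 2 O 0 0 S Q1
ATOM 3 C 0 1 C1 Q1
ATOM 4 N 0 2 C1 P
SITE
. 2 0 0
2 . 0 0
0 0 . 1
0 0 1 .
DELTA
0 -2 0 1
-2 0 2 0
0 2 0 -1
1 0 -1 0
HDELTA 1 0 -1 0
COSUB C1 CC(N)C(=O)O
COPROD Q1 CC(=O)C(=O)O
END

RULE r5_methylester_hydrolase
EC 3.1.1
NAME methyl ester hydrolysis to acid and methanol
ATOM 1 C 0 0 S P
ATOM 2 O 0 0 S P
ATOM 3 O 0 0 S Q1
ATOM 4 C 0 3 S Q1
ATOM 5 O 0 2 C1 P
SITE
. 2 1 0 0
2 . 0 0 0
1 0 . 1 0
0 0 1 . 0
0 0 0 0 .
DELTA
0 0 -1 0 1
0 0 0 0 0
-1 0 0 0 0
0 0 0 0 0
1 0 0 0 0
HDELTA 0 0 1 0 -1
COSUB C1 O
COPROD Q1 CO
END

RULE r6_amidase
EC 3.5.1
NAME primary amide hydrolysis to acid and ammonia
ATOM 1 C 0 0 S P
ATOM 2 O 0 0 S P
ATOM 3 N 0 2 S Q1
ATOM 4 O 0 2 C1 P
SITE
. 2 1 0
2 . 0 0
1 0 . 0
0 0 0 .
DELTA
0 0 -1 1
0 0 0 0
-1 0 0 0
1 0 0 0
HDELTA 0 0 1 -1
COSUB C1 O
COPROD Q1 N
END

RULE r7_decarboxylase
EC 4.1.1
NAME carboxylic acid decarboxylation
ATOM 1 C 0 0 S P
ATOM 2 C 0 0 S Q1
ATOM 3 O 0 0 S Q1
ATOM 4 O 0 1 S Q1
SITE
. 1 0 0
1 . 2 1
0 2 . 0
0 1 0 .
DELTA
0 -1 0 0
-1 0 0 1
0 0 0 0
0 1 0 0
HDELTA 1 0 0 -1
COPROD Q1 O=C=O
END

RULE r8_dehydratase
EC 4.2.1
NAME alcohol dehydration to alkene
ATOM 1 C 0 1 S P
ATOM 2 C 0 0 S P
ATOM 3 O 0 1 S Q1
SITE
. 1 0
1 . 1
0 1 .
DELTA
0 1 0
1 0 -1
0 -1 0
HDELTA -1 0 1
COPROD Q1 O
END
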