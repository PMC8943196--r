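---
title: "Methods: rule-based reaction prediction and conserved-atom-ratio networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based reaction prediction and conserved-atom-ratio networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`carnet` implements the computational core of large-scale retrobiosynthesis
resources: a compound/reaction unification layer, a generalized
reaction-rule engine operating on bond-electron matrices (BEM), a
network-expansion driver, a conserved-atom-ratio (CAR) weighted
biotransformation graph with graph-theoretic characterization, and a
k-shortest-path pathway search with a benchmarking and
reaction-reconstruction harness. This vignette records the model, its
assumptions, the tunable parameters, and the design decisions taken where
the problem was genuinely open.

# Compound unification

Two structure strings denote the same compound when their canonical keys
agree. The key is an OpenBabel canonical SMILES computed after a fixed
normalization:

* **Stereochemistry is stripped** (tetrahedral marks and cis/trans bond
  slashes). The package works on 2D constitutions only; stereoisomer
  expansion is left to external tools.
* **Aromaticity is perceived** before canonicalization, so different
  resonance/kekule drawings collapse.
* **Simple charge states are neutralized**: a -1 center on O, S or N gains
  a proton; a +1 center on N, O or S that carries at least one proton loses
  one. Quaternary cations (for example the pyridinium nitrogen of NAD+) and
  metal ions are untouched, because no proton move can neutralize them.
  No procedure for merging dissociated states is canonical in the
  literature; this rule is the smallest one that merges carboxylate/
  carboxylic-acid and ammonium/amine pairs, and it is applied uniformly.

Compounds must be single-fragment structures with at least one heavy atom
and no wildcard atoms; salts (multi-fragment records), repeat-unit
(polymer) notations and unparsable strings are rejected with
machine-readable reason codes. When merged records disagree on the scope
label, the strongest wins (`biological > bioactive > chemical`),
mirroring the convention that an entry found in a biological database
outranks its bioactive or chemical duplicates. Molecular weights use
standard (not monoisotopic) atomic masses.

Reaction identity is the pair of canonicalized reactant and product
multisets, insensitive to direction (rules are bidirectional, so A => B and
B => A describe one biotransformation); the stored orientation puts the
lexicographically smaller side first. Transport reactions (identical
multisets on both sides) and stereo-only reactions (sides identical after
stereo stripping) are filtered: only reactions that change atom
connectivity are kept. Elemental balance is checked strictly, hydrogen
included; nothing is auto-completed with implicit protons, because balance
is treated as a quality-control category, not a defect to repair.

# The rule engine

A reaction rule is a reactive-site pattern plus a rewrite:

* pattern atoms with element, formal charge and a minimum hydrogen count;
* a symmetric **site matrix** giving the required bond order between every
  pattern atom pair (0 = the atoms must not be bonded); the diagonal
  (non-bonding electrons) is unconstrained in this dialect;
* a symmetric integer **difference matrix** added to the mapped bond
  orders, plus a per-atom hydrogen delta;
* fixed co-substrate and co-product molecule templates (for example the
  O2/H2O2 redox carrier pair).

The reverse rule is `(site + delta, -delta)` with hydrogen deltas negated
and co-substrates/co-products swapped, so every rule is usable in both
directions. Rule validity (symmetry, bond orders within 0..3 on both
sides, non-negative hydrogens) is enforced at load time.

**Matching.** A reactive site is an injective map from the pattern's
substrate atoms to molecule atoms preserving elements, charges, minimum
hydrogen counts and all pairwise bond orders, evaluated over the union of
all kekule structures. Kekule enumeration keeps every atom's total
bond-order sum fixed and reassigns orders only on ring bonds of order 1 or
2: benzene yields 2 assignments, naphthalene 3, non-aromatic molecules
exactly 1. This matters because a rule written against a localized C=C
must see aromatic bonds in whichever alternation exposes them.

**Site deduplication.** Maps are reduced by the automorphism group of the
*pattern*: two maps that place the same atoms in roles exchanged by a
pattern symmetry are one site. Molecule-level symmetry is deliberately not
quotiented out: the two hydroxyl carbons of 1,3-propanediol are equivalent
by molecular symmetry but are reported as two sites, since they are
distinct atoms (and applying the rule at either produces the same reaction,
which the reaction-level deduplication collapses anyway). Maps found in
several kekule forms are reported once.

**Application** adds the difference matrix at the mapped atoms, applies
the hydrogen deltas, appends the co-substrate templates, and splits the
result into connected fragments, each canonicalized like any other
compound. Applications that would create a negative bond order, a negative
hydrogen count or an impossible valence are discarded with a
`valence_violation` reason. Because the rewrite moves bonds and hydrogens
but never creates or destroys atoms, every generated reaction is
elementally balanced by construction - this is asserted, not assumed, in
the test suite. The application also returns the full atom map, from which
the conserved-atom count of every substrate-product fragment pair is read
off directly.

**The toy library.** The 8 bundled rules (alcohol oxidase 1.1.3, aldehyde
oxidase 1.2.3, O-methyltransferase 2.1.1, transaminase 2.6.1, methyl ester
hydrolase 3.1.1, amidase 3.5.1, decarboxylase 4.1.1, dehydratase 4.2.1)
were hand-derived and verified by manual BEM arithmetic. Choices worth
recording: the generic redox carrier is the O2/H2O2 pair (oxidase-style
chemistry) so that every co-substrate is a well-formed compound with at
least one heavy atom; the amino donor is the 2-aminopropanoate/pyruvate
pair; the ester rule is specialized to methyl esters so that its reverse
(esterification with methanol) remains a single-substrate rule. Rules with
a variable second substrate (general esterification, aldol chemistry) are
out of scope: every co-substrate is fixed by the rule.

# Expansion

`expand()` attempts every (rule, direction, compound, site) application
once. Generated reactions are deduplicated by reaction identity against
the known set and against each other; on a collision only the rule id is
appended. Products never seen before are admitted as new chemical-scope
compounds with ids derived from an FNV-1a hash of their canonical key, so
runs are reproducible without any random state. A reaction whose
participants are all biological/bioactive lands in the bio scope;
any chemical or novel participant sends it to the chem scope; the two
collections partition the generated set. One call performs one
generation; iterating on the augmented output expands further shells.

# The CAR network

For a substrate-product pair with `n_c` conserved heavy atoms, `n_r` and
`n_p` heavy atoms on either side:

    CAR_r = n_c / n_r,   CAR_p = n_c / n_p,
    CAR   = (CAR_r + CAR_p) / 2,   distance = 1 / CAR

Hydrogens are always excluded. The surrounding literature also describes a
correction factor that penalizes pairs whose common atoms are few relative
to the molecule sizes, but the displayed defining equation is the plain
mean; `compute_car()` therefore implements the mean exactly and exposes
the correction as an optional multiplier hook defaulting to 1. Note the
consequence: very small molecules (water, CO2) form high-CAR edges with
almost anything, so currency metabolites act as hubs unless excluded
downstream.

`n_c` resolves through a five-stage cascade, in order:

1. **Rule atom map** - exact, used for all rule-generated reactions.
2. **Cofactor-pair table** - an editable TSV of standard pairs
   (NAD(P)+/NAD(P)H, ATP/ADP/AMP, CoA/acetyl-CoA, ...) assumed to conserve
   every heavy atom of the smaller partner; NAD+/NADH therefore has
   CAR = 1 over its 44 heavy atoms.
3. **Maximum common substructure** - the largest common induced subgraph
   with matching elements (bond orders are not compared, so oxidized and
   reduced forms of one skeleton share all atoms), computed as a maximum
   clique of the modular product graph with isomorphism/containment fast
   paths. Molecules above `mcs_max_atoms` (default 60) heavy atoms, or
   pairs whose product graph exceeds 2000 vertices, fall through.
4. **Formula bound** - element-wise minimum of the two compositions,
   hydrogens excluded (C6O is conserved between C7O and C6O2, giving
   n_c = 7, CAR = 0.875, distance = 8/7).
5. **Zero** - no edge.

Every stage is symmetric in its arguments, and the provenance
(`car_source`) is recorded on each edge.

The network is an undirected graph over compounds; every reactant-product
pair of every reaction with positive CAR becomes an edge, and parallel
biotransformations collapse onto one edge carrying all backing reaction
ids and the *maximum* CAR over them - a pathway should be allowed to use
the best-conserving mechanism available. For component/diameter analysis,
edges with CAR below 0.34 are removed (strictly below: 0.34 itself
survives; the threshold is the published value that best reproduces
manually curated "main" reactant pairs) and weights are dropped; isolated
nodes are retained. Diameter and average path length are defined on the
largest component only (eccentricities are infinite across components);
they are exact up to a 2000-node main component and estimated from 200
evenly spaced BFS roots above it, with the estimate flagged.

# Pathway search and benchmarking

`k_shortest()` is Yen's loopless k-shortest-path algorithm over the
distance weights. Determinism is guaranteed by construction: the base
shortest path walks a distance-to-target field choosing the
lexicographically smallest admissible neighbour (tolerance 1e-9 on weight
sums), and candidate ties are broken by the lexicographic node sequence.
Ranked pathways carry per-step CARs, total distance (the sum of 1/CAR) and
the CAR product.

Reference pathways given as reaction sets are **linearized**: all
substrate-product pairs become unit-distance edges, the bundled common
cofactor list (NAD(P)(H), ATP/ADP/AMP, water, O2, H2O2, CO2, ammonia,
phosphate; editable) is excluded to prevent shortcuts through currency
metabolites, and the longest of all-pairs shortest paths - the longest
branch of a branched pathway - becomes the reference, its endpoints the
precursor/target pair. Ties take the lexicographically smallest endpoint
pair and path. `rank_native()` first verifies that every reference edge
exists in the network, then searches until the native node sequence
appears (either traversal direction) or `k_max` (default 100, comfortably
above the ranks that matter in practice) is exhausted.

The eight curation criteria for candidate benchmark pathways are applied
by `filter_benchmark()`: at least two reactions; no transport or
electron-transfer reactions (EC classes 1.9x/1.18-1.20 plus an explicit
flag, since no structural definition exists); all reactions resolvable;
no undefined, non-carbon, protein, RNA or unknown compounds (non-carbon is
detected from structures, the rest come as annotation flags); not
circular; and not polymerization, light-dependent or superpathway records
(flags - these are source-database annotations that cannot be inferred
from structures).

**Reaction reconstruction** classifies how a known reaction is recovered
by a rule-derived network: `exact` when its identity signature is in the
network's reaction set; otherwise every *main pair* (CAR >= 0.34) must
connect - a single step backed by other reactions is classified
`alternative_cofactor` (same main biotransformation, different
co-substrates), and shortest paths of 2..4 steps whose CAR product stays
at or above 0.34 give `multi_step`, the reaction taking the worst
(maximum) step count over its main pairs. Anything else is
`not_reconstructed`.

# Synthetic data

`make_toy_universe(n_bio, n_chem, seed)` draws a deterministic universe
from a hand-curated pool of ~60 named structures (all of 14 heavy atoms or
fewer). The biological selection always starts with the co-substrate core
- water, O2, H2O2, ammonia, methanol, 2-aminopropanoate, pyruvate, CO2 -
because these currency species appear in every metabolic database and the
rule library needs them to fire; the remainder is sampled from the
metabolite-like pool, and the chemical side from a xenobiotic-like pool.
Known reactions are curated templates included when all their participants
were drawn. The default conditions (10 biological, 5 chemical compounds,
seed 7) keep every exhaustive oracle in the test suite tractable.

The generator emulates the *structure* of the real problem - scope labels,
duplicate and multi-source records, orphan compounds, balanced known
reactions - but not the scale or composition of real databases: no
stereochemistry, no charged cofactor chemistry beyond the neutralization
rule, molecule sizes far below natural-product space, and a rule library
of 8 instead of several hundred. Passing tests therefore demonstrate
correctness of the algorithms under controlled conditions, not predictive
performance on real metabolic data.

# Numerical choices and limitations

* Floating-point path-length ties use a 1e-9 (search) / 1e-12 (candidate
  ordering) tolerance; all other arithmetic is integer.
* Kekule enumeration is capped at 1000 assignments; the exhaustive
  matching oracle refuses molecules above 14 heavy atoms, the path
  enumeration oracle graphs above 12 nodes, the BFS oracle above 250 -
  these ceilings prevent accidental combinatorial blowups, and the test
  suite stays within them by construction.
* The MCS stage is an estimator: bond orders are ignored and the
  containment fast path accepts non-induced embeddings, both deliberate
  (atom conservation, not bond conservation, is the quantity of interest).
* The balance checker never adds implicit protons, so reactions written
  without their proton bookkeeping are reported unbalanced rather than
  silently fixed.
* Problem sizes in the tests (universes of ~15-50 compounds, graphs of up
  to 200 nodes, 200 random search instances) were chosen as the smallest
  sizes at which every property is exercised against an exhaustive oracle.
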