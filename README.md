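# basenet

Annotation and search of hydrogen-bonded base interaction networks in RNA
3D structures.

Tight clusters of nucleobases joined by an unbroken network of base–base
hydrogen bonds — triples, quadruples, up to sextuples — stabilize RNA
tertiary structure and often mark functional sites. `basenet` finds and
annotates these networks in PDB coordinate files. It is aimed at RNA
structural biologists who want an accounting of every base cluster in a
structure, a way to query specific arrangements (e.g. "an all-guanine
quadruple with one base bonded to three others"), and an atomic-level
listing of how the bond network changes between two related structures
(mutant vs wild-type, ligand-bound vs free).

## Method

The pipeline is graph-theoretic rather than geometric:

1. **Hydrogen-bond detection.** Base-moiety heavy atoms are extracted from
   one model of a PDB file (hydrogens stripped, alternate locations
   resolved by occupancy). A donor atom D with covalent antecedent DD and
   an acceptor A with antecedent AA on a *different* base form a bond when

   ```
   d(D,A) <= 3.9 Å,   angle(DD–D–A) >= 90°,   angle(D–A–AA) >= 90°
   ```

   the classical heavy-atom criteria; all thresholds are configurable.
   Donor/acceptor inventories follow standard base chemistry (A: N6 donor;
   N1, N3, N7 acceptors; G: N1, N2 / O6, N3, N7; C: N4 / O2, N3;
   U: N3 / O2, O4) and extend to modified bases such as pseudouridine.
2. **Connection table.** The bond list becomes a graph: one node per
   participating base (numbered by an internal residue number, IRN), one
   edge per bonded base pair carrying the bond count and signed atom-pair
   codes. The code `-1604 1311` on a U listing its A partner reads: the
   partner's N6 (element digit 1 = N, position 6) donates to my O4
   (0 = O, position 4), and my N3 donates to the partner's N1.
3. **Pattern search.** Query shapes are the free trees on 2–6 nodes
   (1 pair, 1 triple, 2 quadruples, 3 quintuples, 6 sextuples, enumerated
   with AHU canonical forms). Nodes carry a base label or a wildcard; edges
   carry a bond-count constraint (default: at least one). An Ullmann
   subgraph matcher with compatibility-matrix refinement finds every
   embedding under monomorphism semantics — extra bonds among matched bases
   are allowed, so a quadruple is still found when it is part of a larger
   octuple — and order-permuted duplicates of the same base set are
   filtered out.
4. **Structure diffing.** Two structures processed with identical criteria
   are compared bond-by-bond under an identity residue mapping, yielding
   the bonds exclusive to each and the shared set.

A synthetic fixture generator closes the loop for testing: it places
idealized planar base templates so that a *prescribed* bond network holds
by construction, so every stage is verifiable without any database access.

## Worked example

The classic A9·A23·U12 base triple of yeast tRNA-Phe, reconstructed from
idealized geometry and pushed through the whole pipeline:

```r
library(basenet)

pdb <- generate_fixture(demo_triple_spec())      # synthetic PDB text
s   <- parse_structure(paste(pdb, collapse = "\n"))
hb  <- detect_hbonds(s)
hb
#> 4 base-base hydrogen bond(s)
#>   A9 N6 -> A23 N7  3.38 A
#>   A23 N6 -> A9 N7  3.41 A
#>   A23 N6 -> U12 O4  3.43 A
#>   U12 N3 -> A23 N1  3.40 A

tab <- build_table(hb)
tab
#> connection table: 3 base(s), 4 hydrogen bond(s) on 2 edge(s)
#>   NODE 1 A A:9 1
#>     2 2 1617 -1617
#>   NODE 2 A A:23 2
#>     1 2 -1617 1617
#>     3 2 1604 -1311
#>   NODE 3 U A:12 1
#>     2 2 -1604 1311
```

A23 is the hub: two partners (A9 and U12), two bonds each. From U12's
listing, `-1604 1311` is exactly the pair "partner N6 donates to my O4;
my N3 donates to partner N1". Querying the triple as a labeled tree:

```r
q <- make_query(enumerate_trees(3)[[1]], c("A", "A", "U"),
                constraints = list(2, 2))   # hub first, exact 2 bonds/edge
hits <- filter_redundant(match_pattern(tab, q), q)
length(hits)
#> [1] 1
hits[[1]]$bases$label
#> [1] "A9"  "A23" "U12"
```

The same machinery from a shell:

```sh
basenet fixture triple.yaml -o triple.pdb
basenet hbonds triple.pdb
basenet scan triple.pdb --sizes 2-3
basenet diff wildtype.pdb mutant.pdb
```

(`basenet` is the installed `exec/basenet` launcher; every subcommand is a
thin wrapper over the functions above.)

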