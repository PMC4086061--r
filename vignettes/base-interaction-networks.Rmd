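---
title: "Annotating hydrogen-bonded base interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating hydrogen-bonded base interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basenet)
```

## The problem

RNA tertiary structure is held together to a large degree by hydrogen
bonds between nucleobases. Beyond the canonical pairs of the secondary
structure, bases form triples, quadruples and larger clusters in which an
unbroken network of base–base bonds ties three to six (occasionally more)
residues together. These clusters stabilize folds, build ligand pockets
and are plausible tertiary motifs, yet they are awkward to find with
alignment- or geometry-based tools: what defines them is not a spatial
arrangement but the *topology* of their bond network.

`basenet` treats the problem graph-theoretically. A structure becomes a
graph whose nodes are bases and whose edges are hydrogen-bonded base
pairs (with bond multiplicities); a query is a small labeled tree; search
is subgraph matching. This vignette explains each model choice, the
tunable parameters, what the synthetic test data does and does not
emulate, and the package's known limitations.

## Hydrogen-bond model

Deposited crystal structures carry no hydrogens, and we strip hydrogens
from NMR models as well so that a single criterion applies to every input.
A donor–acceptor contact between atoms of two *different* bases is
accepted as a hydrogen bond when three heavy-atom conditions hold:

* donor–acceptor distance $d(D, A) \le$ `max_da_distance` (default
  **3.9 Å**);
* angle at the donor, $\angle(DD, D, A) \ge$ `min_ada_angle` (default
  **90°**), where $DD$ is the donor's covalently bonded ring antecedent —
  this is the heavy-atom proxy for the usual $D\!-\!H\cdots A$ angle,
  necessary because no hydrogen positions exist;
* angle at the acceptor, $\angle(D, A, AA) \ge$ `min_daa_angle` (default
  **90°**), with $AA$ the acceptor's antecedent.

The defaults are the classical heavy-atom cutoffs used throughout the
hydrogen-bond-annotation literature; they are deliberately permissive
(the point is an *accounting* of plausible bonds, not an energy model) and
all three are configurable per run or via a YAML config file. Where an
atom has two ring neighbours, the lower-numbered one serves as the
antecedent; at a 90° threshold the choice is immaterial in practice.

Donor/acceptor inventories follow standard base chemistry: A donates from
N6 and accepts at N1, N3, N7; G donates from N1, N2 and accepts at O6,
N3, N7; C donates from N4 and accepts at O2, N3; U donates from N3 and
accepts at O2, O4. C–H···O interactions are not counted. Modified bases
are first-class: pseudouridine (whose C-glycosidic link frees N1 to
donate) plus the common methylated and 2'-O-methyl species (1MA, 5MC,
2MG, M2G, 7MG, OMC, OMG, H2U, 5MU) ship in the library, with donor sets
adjusted where methylation removes an imino or amino proton. Unknown
residues are dropped, never guessed; the library is user-extensible so a
new modification is one config entry, not a code change.

Only the base moiety enters the analysis: ring atoms and exocyclic
substituents. Ribose (including O2') and phosphate atoms are excluded by
construction, because the object of study is the base–base network;
base–backbone bonds are a different annotation problem.

Sequence-adjacent bases are *not* excluded. Neighbouring bases rarely
satisfy the geometry, and where they do the bond is a genuine part of the
network.

## Connection tables

The detected bonds are recast as a connection table: one node per base
participating in at least one bond, one edge per unordered base pair. A
node's internal residue number (IRN) is its 1-based rank among
participating residues in structure order; the author identity
(chain, residue number, insertion code) is carried alongside, so the
numbering is unambiguous even for renumbered or multi-chain files.

Each edge lists its bonds as signed four-digit codes from the perspective
of the listing node: donor element digit (1 = N, 0 = O), donor atom
position, acceptor element digit, acceptor atom position, negative when
the *partner* is the donor. A uridine listing `-1604 1311` therefore
receives N6→O4 and donates N3→N1. Atom positions above 9 (possible in
exotic modifications) cannot be packed into one digit; such bonds fall
back to an explicit `DONORATOM>ACCEPTORATOM` token. The text format
round-trips losslessly at the graph level; a JSON twin carries distances
and full atom detail.

## Query patterns and search

Because bond networks in structures are overwhelmingly sparse, query
shapes are the *free trees* on 2–6 nodes: 1 pair, 1 triple, 2 quadruples,
3 quintuples, 6 sextuples. The enumerator grows trees by leaf attachment
and collapses isomorphs with an AHU canonical form rooted at the tree
centre; the resulting canonical-code order fixes the "type I, II, ..."
ordinals deterministically. Since any such numbering is arbitrary, every
report also prints the degree sequence (a star-quadruple is "3,1,1,1"),
which identifies the shape without reference to the ordinal. The
enumerator accepts larger sizes (11 septuples, checked against a
Prüfer-sequence brute-force census in the tests).

Queries attach to each node a base label or a wildcard and to each edge a
bond-count constraint: the default `any` means "at least one bond"; an
integer `k` means exactly k; `">=k"` means at least k. Matching is
Ullmann's algorithm — a boolean compatibility matrix over
(query node, base) pairs, pruned by label, degree and iterated
neighbourhood support, then completed depth-first with re-refinement and
ascending-IRN tie-breaking for determinism.

Two semantic decisions matter:

* **Monomorphism, not induced subgraph.** Extra bonds among the matched
  bases do not disqualify a match. This is what lets each of two
  interconnected quadruples be found on its own inside the octuple they
  jointly form; an `induced = TRUE` mode provides the stricter semantics.
* **Redundancy filtering.** A symmetric query retrieves the same base set
  once per compatible node ordering (a star-quadruple six times, once per
  leaf permutation). Hits are reported per distinct base set, represented
  by the lexicographically smallest assignment, with the collapsed count
  retained.

Overlapping hits across patterns are all kept, and a post-processing step
reports connected unions of hits — hit base sets that overlap or are
bridged by a bond — which is how composite networks such as the
quadruple-pair octuple surface without a dedicated octuple query.

## Comparing two structures

For two structures processed with identical criteria, bonds are
identified by (donor residue, donor atom, acceptor residue, acceptor
atom) and residues are paired by identical author identity — the intended
use is *very similar* structures (mutants, ligand states), where author
numbering agrees. The report partitions bonds into A-only, B-only and
shared (with both distances); bonds touching residues present in only one
structure are flagged. Sequence-alignment-based residue mapping is out of
scope.

## Synthetic fixtures: what they do and do not show

The package must be testable end-to-end without downloading structures,
so the fixtures module *constructs* PDB files realizing a prescribed bond
network. Idealized planar base templates (standard aromatic geometry,
frozen as coordinate constants) are rigidly placed in one plane along a
spanning order of the intended tree. For each intended contact the
template is posed so the donor–acceptor pair sits near 2.9 Å (Gaussian
jitter, s.d. 0.05 Å by default, with fallback targets up to 3.4 Å when
a rigid two-point fit requires it) with compliant approach angles, while
every *non-intended* donor/acceptor distance between non-bonded bases is
kept beyond the cutoff plus a 1 Å margin and steric overlap below 2.4 Å
is rejected. Placement is a backtracking search (candidate contact-atom
combos × direction fan × spin), expanding the heaviest subtrees first and
steering each new base away from the placed crowd; marginal cases get
randomized restarts, all of it deterministic given the spec seed.
Unrealizable specs fail with an explicit infeasibility error rather than
a silent wrong fixture.

Planarity makes feasibility stricter than real chemistry (real clusters
bend out of plane). Two findings from exercising the generator are worth
recording. First, a star of five partners around one base could not be
realized in the plane — consistent with such sextuple arrangements being
absent from solved structures. Second, pyrimidines, whose three
hydrogen-bonding atoms sit on one rim of the ring, cannot commit two
atoms to a double-bonded partner while also serving another neighbour.
The random-spec sampler used by the property tests therefore draws from a
family the generator always places: trees of 2–6 bases with node degree
≤ 3, inventories covering degrees, and at most one 2-bond edge whose
endpoints are leaves or purines of degree ≤ 2. Multi-bond hubs are still
exercised — the demo A·A·U triple has a hub with two 2-bond edges — just
not sampled randomly.

What passing these tests shows: detection, table building, search and
diffing are exact on geometry that satisfies the stated criteria by
construction. What it does not show: robustness to the noise, disorder,
non-planarity and crowding of real crystallographic data. The two demo
motifs (`demo_triple_spec()`, `demo_octuple_spec()`) are idealized
*reconstructions* of well-known interactions — the A9·A23·U12 triple of
yeast tRNA-Phe and the interlocked GGGG/CUCU quadruples of lysine
riboswitch structures — not the deposited coordinates.

## Numerical and design notes

* Alternate locations: highest occupancy wins, ties resolve to altloc
  `A`, then lexicographically. The rule is a determinism choice.
* Multi-model files: exactly one model is analysed per run, selected by
  MODEL number; hydrogens are stripped for all inputs.
* DNA residues are excluded by default (`include_dna = TRUE` maps
  DA/DC/DG/DT onto A/C/G/T chemistry).
* All inter-chain base pairs within the retained chains enter one graph;
  chain boundaries do not partition the network.
* Detection prefilters base pairs by centroid distance (cutoff + 6 Å, an
  upper bound on twice the base radius); tests assert equality with the
  naive all-pairs scan.
* The exhaustive-assignment oracle for the matcher, the Prüfer-sequence
  census for the tree enumerator and an external graph library are kept
  strictly test-side; the package's own algorithms never call them.
* Problem sizes in the test battery — 200 random graphs of ≤ 10 nodes for
  matcher/oracle agreement, 100 random specs for the fixture round-trip —
  were chosen to exercise the combinatorics densely while keeping the
  whole suite in the low minutes on one core.

## Limitations

* No base–ribose or base–phosphate bonds, no water-mediated bonds, and no
  Leontis–Westhof edge/orientation classification — the annotation is
  purely topological.
* No geometric similarity scoring: two hits with the same network but
  different 3D shapes are the same thing to this tool.
* The two-structure diff assumes identical author numbering; renumbered
  pairs need external renumbering first.
* Query shapes are trees; cyclic bond networks are found only insofar as
  their spanning trees match (the monomorphism semantics guarantees they
  are found, but they are not distinguished as cycles).
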