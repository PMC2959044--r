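---
title: "Methods: homeodomain repertoire classification and paralog retention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homeodomain repertoire classification and paralog retention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeorep)
```

This vignette documents the models, rules and numerical choices behind
`homeorep`, in the spirit of a methods section: what each statistic assumes,
which knobs matter, and what a green test does and does not establish.

## The 60-column homeodomain frame

Everything in the package operates on homeodomains normalized to the same
60 alignment columns (1-based). Raw sequences can be longer: typical
TALE-class homeodomains are 63 residues because of a three-amino-acid
insertion in the loop between helices 1 and 2, and a few atypical
homeodomains carry other short insertions. `normalize_tale()` and
`excise_insertions()` remove declared insertion content and keep it on the
record, losslessly — `reinsert_insertions()` restores the raw sequence
exactly, and the test suite asserts this round trip on randomized inputs.

**Insertion coordinates.** Catalog notation such as `insert(NLA) 23` gives
the raw position where the inserted content *starts*. Internally an
insertion is stored as `after_column = 22`: the last normalized column that
precedes it. One convention is used everywhere; display and catalog output
add the 1 back. The structural windows used by `classify_insertion()` are
expressed in the same coordinates: the helix-1/2 loop spans after-columns
20–25, helix 3 spans 31–45. Exactly one 3-residue loop insertion is the
TALE-typical pattern; any other loop insertion is atypical; there is no
automatic insertion inference — positions come from the catalog or caller,
because placing them correctly is an expert-alignment decision, not an
algorithmic one.

Residues are upper-cased; anything outside the 20 amino acids, `-` and `X`
becomes `X` with a warning. Gaps and `X` are excluded from both signature
matching and distance computation — they are absence of evidence, never
evidence.

## Diagnostic signatures and class assignment

A signature is a position-anchored run of per-column constraints in bracket
notation (`[AKST]` allowed set, `[^DGHM]` disallowed set, bare letter =
fixed residue), shipped as a plain TSV (`inst/extdata/signatures.tsv`) so
the exact transcriptions are inspectable and versioned. The shipped set:
NKL at columns 41–45, HOXL at 46–58, HOXL2 at 16–19, the PRD (paired) block
at 16–26, and the SIX1/2 family `ETSY` at 3–6 (implemented as an exact
match; whether conservative substitutions should be tolerated is unstated
in the source material, so the strict reading was chosen).

A gap or `X` anywhere in a signature window fails the match: signatures are
presence claims, and no partial credit is given. The number of k-mers
matching a signature equals the product of per-column admissible-set sizes
(`signature_match_count()`); the tests verify this against exhaustive
enumeration wherever $20^w$ is tractable ($w \le 5$, including the NKL
window: 80 of $20^5$) and column-wise for the wider windows, plus agreement
with an independent regular-expression oracle on 10,000 random windows per
signature.

`assign_class()` collects five kinds of evidence and resolves the class by
fixed precedence:

1. **secondary domains** (SIX → SINE, POU-specific → POU, LIM → LIM,
   PBC/MEIS → TALE, octapeptide/paired → PRD),
2. **insertion** (a TALE-typical loop insertion → TALE),
3. **tree placement** (a caller-supplied hint),
4. **signatures** (NKL/HOXL/HOXL2 → ANTP, PRD block → PRD, ETSY → SINE),
5. **introns** (the PRD-characteristic intron at the codon 46/47 boundary).

The ordering mirrors observed curation practice — an upstream SIX domain
outweighs an NKL signature match — and every evidence item is emitted, so a
lower-precedence disagreement sets `conflict = TRUE` rather than vanishing.
A record with no evidence at all is UNCLASSIFIED with an empty evidence
list. Subclasses: within ANTP, an NKL signature wins; HOXL/HOXL2 without
NKL mark extended-Hox-related genes. Within PRD, the subclass is the
position-50 call (Q50/K50/S50); a gap or `X` at column 50 gives UNKNOWN and
no subclass. Position-50 lysines in SINE-class genes are characteristic of
that class and deliberately never counted toward the PRD K50 row of the
presence matrix.

**Octapeptide scoring.** The source material gives examples of "clear" and
"possible" octapeptides but no rule, and its informal description is not
self-consistent, so the scanner applies a documented stand-in: over each
8-mer window, require at least two of positions 5–8 in {L, I, V} with an
exact L at position 6 or 7; score the number of positions among {3, 6, 7}
holding a residue from {L, I, V}; 3 is CLEAR, 2 is POSSIBLE. Both printed
clear octapeptides (SSISSLLS, HSIDDILG) score 3 under this rule. The rule
is an artifact definition, not a biological claim, and both printed
"possible" octapeptides happen to score 3 too — the CLEAR/POSSIBLE boundary
should not be over-interpreted.

**Table-3-style presence matrix.** `build_presence_matrix()` reports
PRESENT/ABSENT per class and subclass per species, in the conventional row
order (ANTP with Hox, ParaHox, Extended Hox, NKL rows; PRD with Q50, S50,
K50; then the remaining classes). A class row with any PRESENT subclass is
itself PRESENT, and adding assignments can never flip PRESENT to ABSENT.
The published table header labels one PRD row "N50" where the surrounding
text discusses S50; this package uses S50 throughout.

## Distances and neighbor joining

`compute_distances()` uses pairwise deletion (columns with `-`/`X` in
either sequence are dropped from numerator *and* denominator) and, by
default, the Poisson correction $d = -\ln(1 - p)$. The historical analysis
used a distance-tool default (JTT-style) protein model; that model is not
re-implemented. Rationale: the downstream statistics — clade counts and
*relative* branch lengths — depend on tree shape far more than on the exact
exchangeability matrix, and the Poisson form is deterministic and
dependency-free. Consequence: published branch-length values are reproduced
exactly only from a published tree file, never by re-estimation from
sequences. A saturated pair ($p = 1$) has no finite Poisson distance; it
yields `Inf` with a warning and downstream tree building refuses the
matrix. A pair with zero comparable columns is an error naming the pair.

`neighbor_joining()` is the standard Saitou–Nei agglomeration with the
Q-criterion and two-point branch-length formulas, written in-package (the
`ape::nj()` implementation serves as an independent cross-check in the test
suite, never as the implementation). Numerical choices:

* ties on the minimal Q (within $10^{-12}$) are broken by the
  lexicographically smallest pair of cluster labels, a cluster being
  labelled by its smallest leaf — the output is deterministic;
* negative estimated branch lengths are clamped to 0; the count is reported
  via a message and as attribute `n_clamped`;
* $n = 2$ joins the two leaves by a path of total length $d_{12}$; $n = 3$
  uses the closed-form star lengths.

On additive (tree-metric) inputs the implementation reproduces the
generating topology and branch lengths to $10^{-9}$; the acceptance suite
checks 200 random instances.

## Midpoint rooting, root-to-tip statistics, clade counting

`midpoint_root()` places the root halfway along the tree's diameter path
(tie on the diameter pair broken lexicographically). If the midpoint falls
exactly on a node (within $10^{-12}$), that node becomes the root — which
can give a root of degree 3; such trees carry an explicit rooted flag,
since `ape::is.rooted()` would call them unrooted. All-zero branch lengths
are a degenerate-metric error: a midpoint is meaningless there, and the
simulator's zero-substitution regime surfaces this error as a flagged
degenerate replicate rather than a silent zero.

Root-to-tip lengths are plain path sums from the root; the per-species
"average branch length" is their arithmetic mean over the leaves sharing a
two-letter prefix. This interpretation (mean root-to-tip distance, not mean
per-edge length) follows the historical computation, which exported
root-tip lengths from a tree-statistics tool and averaged them.

`count_species_specific_clades()` counts *maximal* prefix-homogeneous
clades with at least `min_size` (default 2) leaves: an internal node all of
whose leaves share one prefix, under a parent that is not homogeneous.
Nested homogeneous clades are never double-counted. Counting runs on the
midpoint-rooted tree by convention — the rooting a neighbor-joining
implementation happens to emit is arbitrary, and reproducibility wins;
`relabel_subset()` supports the subset-comparison idiom of replacing part
of one species' prefixes with an unused pseudo-prefix (e.g. `Zz`) so the
subset is reported separately. `build_clade_report()` assembles the
per-species table and appends a grand-mean row (arithmetic means of the
per-species columns).

## Linkage scanning

Records carrying scaffold coordinates (0-based half-open; BED is native)
are scanned per scaffold: every co-located pair is reported with the
nearest-end gap `max(0, later.start - earlier.end)` — the "4.7 KB apart"
convention; since anchor points are not defined in the source material, the
strand-independent nearest-end gap was chosen. Orientation comes from the
strand combination in scaffold order (same strands, convergent `+ -`,
divergent `- +`). Overlapping spans on one scaffold are rejected loudly.
Distances render in kilobases to one decimal.

## The synthetic repertoire world

`simulate_repertoire()` exists so that every pipeline stage has ground
truth without any downloads. Per gene family, a copy process runs along a
fixed species tree: duplications arise at `duplication_rate` per lineage
per unit time anywhere in the tree; losses at `loss_rate` affect only
duplicated copies, never the original lineage copy, so every family retains
one ortholog per species (a documented simplification that anchors the
alignment). Family subtrees join a common repertoire root via stem
branches. Sequences evolve down the gene tree by per-site Poisson
substitution with uniform replacement over the 19 alternatives — not an
empirical exchangeability matrix, deliberately, since the statistics under
test depend on tree shape. Family root sequences descend from a single
repertoire ancestor with `family_divergence` expected substitutions per
site, and class-diagnostic signature motifs are planted into designated
families. Truth is recorded as the true gene tree, true root-to-tip depths,
and the species-specific clade counts implied by the surviving duplication
history (computed on the true tree by the same maximality definition).

The default world and why:

| parameter | default | rationale |
|---|---|---|
| species tree | `((Ml:8,Aq:5):1,Nv:9)` | terminal branches of 5–9 time units; at the default substitution rate, sister species sit 0.5–0.8 expected substitutions/site apart — the divergence scale of real homeodomain repertoires — and per-species depths differ, so rank statistics are meaningful |
| `substitution_rate` | 0.05 /site/unit | "low" relative to the branch lengths: enough signal to resolve species, far from saturation |
| `duplication_rate` | 0.0015 /lineage/unit | duplications are rare discrete events (≈0.3 surviving per repertoire) |
| `loss_rate` | 0.00075 | half the duplication rate |
| `n_families` | 8 | ~24 base records per repertoire |
| `family_stem` | 2.0 | separates families by ≈0.2 subs/site of clock plus the divergence below |
| `family_divergence` | 0.25 subs/site | families divergent but alignable; keeps the deepest pairwise p-distance ≈0.75, well below $p = 1$ where the Poisson correction diverges |

**Why the duplication rate must be low.** With only 60 columns, a
duplication that occurred close to a speciation leaves almost no
substitutions on the internal branch separating the two events, and
distance noise (standard deviation of a p-distance on 60 sites is ≈0.06)
then decides the topology. Empirically each surviving duplication carries
roughly a 5–10% risk of misreconstruction in this world — irreducible at
fixed sequence length. The acceptance suite's recovery check (planted clade
counts recovered exactly in ≥95 of 100 seeded replicates at substitution
rate 0.05) therefore requires a world in which duplications are rare;
equivalently, it is a check that the pipeline adds no error of its own on
top of that information-theoretic floor. An earlier calibration with a
deeper outgroup (11 units) occasionally produced long-branch artifacts —
two deep same-species leaves from different families pairing up — which
violated the companion property that zero duplication rates yield zero
clades; the shipped world shows no such artifact across the tested seeds.

What the generator does **not** emulate: site-rate heterogeneity,
empirical amino-acid exchangeabilities, gene conversion, intron evolution,
secondary-domain gain/loss, and losses of original lineage copies. A green
recovery test therefore establishes that the statistics are computed
correctly and that reconstruction is reliable *in this regime* — not that
60-residue NJ trees resolve any real repertoire.

`simulate_branchlength_study()` is the feasibility companion: per
replicate it simulates, rebuilds the tree from sequences alone,
midpoint-roots it, and tabulates true versus estimated per-prefix mean
root-to-tip lengths (true depths rescaled by the substitution rate onto the
estimated scale). Rank agreement (Spearman) across replicates is the
headline output; the absolute bias is also reported and is expected to be
positive, since family-root divergence inflates estimated depths but is not
part of the gene-tree clock. Zero-substitution worlds produce an all-zero
distance matrix; the replicate is flagged degenerate, estimates are NA.

**Synthetic catalog sequences.** The deposited sequences behind the
packaged 76-gene catalog are not redistributable inside this package, so
`synthesize_catalog_alignment()` fabricates 60-column residues *consistent
with the catalog annotations* (planted signature windows, K50 for SINE, Q50
for PRD and ANTP, G50 for Pbx, masked tails for the two genes documented as
incomplete, printed octapeptides). They are labelled synthetic everywhere
and exist to exercise the classification machinery end-to-end; no
biological conclusion rests on them. Likewise the test suite's stand-in for
the published seven-species tree is built programmatically from the printed
per-species table and is labelled synthetic.

## Determinism and tolerances

Every stochastic component takes a mandatory integer seed; identical
configurations are byte-identical. Fixed tie-breaks: NJ joins and diameter
endpoints by lexicographic label order. Tolerances: $10^{-12}$ for
exact-arithmetic comparisons (Q ties, node-midpoint coincidence),
$10^{-9}$ for additive-recovery and midpoint assertions. Branch lengths are
serialized with `%.17g`, so newick round trips are lossless at double
precision.

## Known limitations

* Classification of records with neither domains, insertions, introns,
  signatures nor tree hints is honest but uninformative: UNCLASSIFIED.
  Tree-placement hints are consumed, not inferred — no tree-based
  classification heuristic is built in.
* The distance model is uniform-Poisson; absolute branch lengths are not
  comparable to JTT-based estimates (relative per-species patterns are the
  supported use).
* The `'*'` marks that appear on some intron positions and accessions in
  the printed catalog have no stated meaning; they are preserved as opaque
  flags. One SINE-class gene mentioned only in the running text (MlSIX45)
  is absent from the printed table; the packaged fixture follows the table.
* Linkage analysis stops at pair reporting; no cross-species synteny or
  cluster-ancestry inference.
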