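---
title: "Methods: sequence similarity networks for desaturase classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence similarity networks for desaturase classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fadssn)
```

## The problem

Membrane-bound fatty acid desaturases form a large superfamily whose
members differ in which lipid carrier they accept (acyl-CoA, acyl-PC,
MGDG, sphingolipid, phospholipid) and where in the acyl chain they place
the double bond.  The superfamily is too divergent for a trustworthy
single multiple sequence alignment, which is exactly the situation
sequence similarity networks (SSNs) were designed for: instead of one
global alignment, every pair of sequences is aligned locally, the
significance of each pairwise alignment becomes an edge weight, and
families emerge as connected components when weak edges are filtered
away.  Because substrate head-group preference segregates by subfamily,
the components at a suitable stringency carry functional meaning, and an
uncharacterized sequence can inherit the consensus annotation of the
cluster it lands in.

## The network model

**Edges.**  For two sequences of lengths $m$ and $n$, the package
computes the exact affine-gap Smith-Waterman score $S$ (Gotoh
three-state dynamic programming; a gap of length $k$ costs
`gap_open` $+ k \cdot$ `gap_extend`), converts it to a bit score

$$S' = \frac{\lambda S - \ln K}{\ln 2}$$

and to a base-10 log E-value over the pairwise search space,

$$\log_{10} E = \log_{10}(m\,n) - S' \log_{10} 2 .$$

Defaults are the standard gapped protein-search settings: BLOSUM62,
gap open 11, gap extend 1, $\lambda = 0.267$, $K = 0.041$; all are
overridable through `scoring_scheme()`.  The search space is the
pairwise $m \cdot n$ rather than a database-wide one: an SSN edge is a
pairwise quantity, and a database-size factor would shift every logE by
the same constant, which the thresholds would simply absorb.  "logE" is
base-10 throughout, so thresholds like $-5$ or $-65$ read as BLAST-style
exponents.  Percent identity on an edge is identical columns divided by
aligned columns (gap columns included), the convention of BLAST hit
reports.

**Nodes.**  Before the all-vs-all stage, near-identical sequences are
collapsed into representative nodes at 60% identity by linear-scan
greedy clustering: records are processed longest-first (ties by
accession), each joins the first node whose *representative* it matches
at or above the threshold, otherwise it founds a new node.  For this
collapse the identity measure is deliberately different from the edge
measure: identical columns divided by the **shorter sequence length**
(the CD-HIT convention, `cluster_identity()`).  The aligned-column
identity of a local alignment cannot be used here — two unrelated
proteins typically share a short local alignment whose column identity
exceeds 60%, so that measure collapses unrelated sequences; with the
CD-HIT denominator a short alignment contributes almost nothing.  The
representative is the longest member (the founder), which best preserves
domain content for the edges computed from it.

**Cytochrome-b5 rule.**  Some desaturases carry a fused cytochrome b5
electron-donor domain.  The fused domain is allowed to contribute to an
edge's E-value only when *every* member protein of both connecting
nodes carries it; any mixed or unfused pair is aligned on the
desaturase-only (trimmed) sequence, with `m` and `n` recording the
lengths actually aligned so the rule is auditable from the edge table.
`all_vs_all()` applies the rule pairwise on whatever records it is
given; `ssn_pipeline()` passes node-level "all members fused" flags so
the network stage matches the node-wise statement of the rule.
Repnode collapse itself always compares full sequences — the collapse
happens at corpus ingest, before any edge-level trimming.

**Thresholds.**  The initial network keeps edges with logE $\le -5$.
Stringency can only increase (`apply_threshold()` refuses to loosen),
which guarantees that every stricter partition refines the looser one —
the filtration property the whole sweep analysis rests on.  Threshold
comparisons are $\le$ on the stated value: scores are effectively
continuous, so the boundary case carries no weight, and $\le$ makes a
preset like $(-13, -20, -30, -56, -65)$ self-consistent.  Cluster labels
are canonical (smallest representative accession in the component), so
partitions are invariant to node input order.  A *major cluster* has
strictly more than 50 member sequences, counting all proteins collapsed
into its nodes.

## Length filter

The corpus filter retains sequences of 250-550 residues by default,
which removes fragments and multi-domain fusions other than the
desaturase + cytochrome b5 pair; a stricter 350-550 window, appropriate
when free cytochrome b5 proteins must be excluded up front, is available
as `length_preset("strict")`.  Both windows are inclusive on both ends.

## Annotation, consensus and classification

Functional labels (kingdom, substrate head-group, regioselectivity,
domain ranges) are *input metadata* joined from a TSV — the package does
not call domains or predict topology.  Cluster consensus substrate is
the strict majority over characterized members only; uncharacterized
members carry no vote, a tie yields `"ambiguous"`, and a cluster with no
characterized member is `"unknown"` with support 0.  Family names are
transferred from curated seed accessions (e.g. an SCD1-like seed naming
the first-desaturase cluster); clusters holding seeds of two families
are flagged `"conflict"`, and seedless clusters receive systematic
rank names.

Query classification is nearest-representative: the query is aligned
against every representative (b5 rule applied pairwise), the minimum
logE wins, and an assignment is made only if it clears the cutoff
(default: the network's stringency).  Ties break by higher percent
identity, then accession.  The reported confidence is the assigned
cluster's consensus support — the inherited claim is the cluster's, not
the pair's, so an E-value transform would overstate certainty.
Lowering the cutoff can only turn an assignment into "unclassified",
never move it between clusters.

The binding-site report (`binding_site_substitutions()`) globally aligns
a reference to a query (end gaps charged — binding residues span the
whole domain, and a local alignment could silently truncate the ends)
and classifies each user-supplied reference position by charge-class
transition.  Charge classes partition the alphabet: positive {K, R, H},
negative {D, E}, polar-uncharged {S, T, N, Q, Y, C}, hydrophobic
{A, V, L, I, M, F, W, G, P}.  Histidine is classed positive by
convention; because desaturase His-box histidines are catalytic rather
than charge carriers, the table is replaceable via `charge_table`.
The residue list itself must come from a solved structure — the package
does not guess binding sites.

## The synthetic superfamily generator

`generate()` plants a star hierarchy: one root sequence, family
ancestors derived by mutating each site independently with probability
`p_family`, subfamily ancestors with `p_subfamily`, tips with `p_tip`,
all under a uniform 20-state model (a substituted site takes any of the
19 other residues uniformly).  Defaults: 4 families x 3 subfamilies x
25 tips of 400 residues with probabilities 0.7 / 0.35 / 0.1, 50
unrelated background sequences, half of family 1 fused with a
90-residue accessory segment recorded as a `cytb5` domain, and 20% of
tips per subfamily (at least one) marked characterized with the
subfamily's substrate.  Those branch probabilities give expected
identities (computable in closed form with `expected_identity()`, which
accounts for back-substitution) of roughly 81% within a subfamily, 35%
within a family, and near-random between families — the tiered structure
an SSN is supposed to resolve, with comfortable margins around the 60%
collapse threshold and the sweep thresholds.

What the generator deliberately does **not** emulate: insertions and
deletions (alignment lengths equal sequence lengths within a family),
site-rate heterogeneity, substitution bias (no BLOSUM-shaped
preferences), or realistic phylogenies (the hierarchy is star-like, not
a birth-death tree).  Passing the planted-recovery tests therefore shows
that the pipeline machinery is correct — filtration, clustering,
consensus, classification — not that any particular threshold is right
for real desaturases, where domain composition, indels and uneven
divergence blur the tiers.

## The recovery experiment and frozen thresholds

`recovery_experiment()` runs the full pipeline on a generated corpus and
scores, at each sweep threshold, the adjusted Rand index (ARI) between
connected components and the planted families, and separately the
planted subfamilies, over planted tips (background sequences have no
planted label and are excluded from the ARI).  It also withholds 20% of
tips *before* the network is built and classifies them against the
strictest partition, reporting the fraction assigned to their planted
subfamily's cluster and the fraction of informative predictions whose
substrate matches the planted label.

The default sweep is $(-13, -100)$.  A pilot sweep of the default
configuration showed within-family (between-subfamily) edges around
logE $-40$ to $-70$ and within-subfamily similarity near $-190$, so
$-13$ sits far below any spurious background association while keeping
families connected, and $-100$ cuts all between-subfamily edges while
far above the level at which a subfamily could fragment.  These two
values were frozen after that pilot and are not tuned per run.  At the
default problem size (290 retained records, 62 representative nodes)
the experiment runs in under a minute on one CPU.

## Companion tree

For sketching structure inside one subfamily cluster,
`distance_matrix()` converts pairwise local-alignment identity $p$ to
$d = -\ln\!\big(\max(p - 0.05,\ \varepsilon)/0.95\big)$ (0.05 being the
random-identity floor of a 20-letter alphabet; $\varepsilon = 10^{-3}$
caps the distance at about 6.86), and `neighbor_joining()` builds the
standard NJ tree, clamping any negative branch length to zero with a
warning.  This is explicitly an approximation: distances come from
pairwise alignments rather than a multiple sequence alignment, the
identity correction is crude at long distances, and no maximum-
likelihood model or bootstrap resampling is involved.  It is intended
for closely related members of a single cluster, where pairwise
identities are high and the approximation is mild; on additive inputs
NJ reproduces every input distance exactly, which the test suite
verifies to $10^{-9}$.

## Numerical and determinism choices

* Smith-Waterman traceback resolves ties deterministically (stop at the
  first zero-contribution predecessor; otherwise prefer match over
  gap-in-subject over gap-in-query), so identity and alignment length
  are reproducible across platforms.
* One alignment per unordered pair, in lexicographic accession order —
  no min/max-of-two-directions ambiguity exists anywhere.
* Greedy clustering order (length, then accession) fixes all ties, so
  the clustering is a pure function of the input *set*.
* Empty optimal alignments (score 0) report length 0 and identity 0;
  in the distance module they land on the capped maximum distance.
* All randomness in the synthetic module flows from the single `seed`
  in `synth_config()`; the same seed yields byte-identical FASTA,
  edge tables, partitions and classification output.

## Known limitations

* Exact DP with no heuristic seeding: all-vs-all cost is quadratic in
  corpus size and sequence length, comfortable up to a few thousand
  sequences, not a BLAST replacement.
* No compositional score adjustment; Karlin-Altschul parameters are
  taken as configuration, not re-estimated from the scoring system.
* Domain ranges are trusted input; there is no HMM scanning, and no
  retrieval from external databases.
* The consensus machinery assumes characterized labels are correct and
  independent; a cluster dominated by one heavily studied lineage will
  look more confident than it should.
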