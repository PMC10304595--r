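---
title: "Methods: profile scanning, typing and trees for p25alpha-family proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile scanning, typing and trees for p25alpha-family proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpppscan)
```

## The problem

The p25alpha domain defines the TPPP (tubulin polymerization promoting
protein) family. Its architecture varies in a small number of recurring
ways, and those architectures — not overall sequence similarity — carry the
biological signal: long-type TPPPs have a ~160-aa domain ending in a highly
conserved block whose most recognisable part is the Rossmann-like
`GxGxGxxGR` motif; short-type TPPPs (~140 aa) lack that block but keep the
`L(V)xxxF(Y)xxF` anchor at the start of the domain and a `GGP` in the
C-terminal half; truncated TPPPs (~120 aa) lack the entire C-terminal
third; apicortins combine a partial p25alpha domain with a DCX domain; and
some proteins carry two p25alpha domains. `tpppscan` turns this typology
into an explicit, tested decision procedure operating on user-supplied
FASTA (protein, or nucleotide contigs translated in six frames).

## Domain detection by scoring profiles

Homologues are found by scanning with position-specific scoring profiles
rather than by remote database search, so runs are self-contained and
deterministic. A profile is built from a small seed alignment: columns with
more than 50% gaps are dropped, and each remaining column scores residue
$a$ as

$$ s_j(a) = \log\frac{(c_{j,a} + \lambda q)/(N_j + \lambda)}{q}, $$

with Laplace pseudocount $\lambda = 1$ and uniform background $q = 1/20$.
`X` (unknown residue) scores 0 everywhere, i.e. neutrally. Sequence
weighting schemes are omitted on purpose: seed sets are small and curated,
and the added machinery would not change the downstream calls.

Scanning finds the best local profile-to-sequence alignment under affine
gap penalties (open 11, extend 1 — the familiar BLAST scale), reports it if
it reaches the profile threshold, masks its span and repeats; hits are
therefore non-overlapping by construction. There is no hard cap on gap
length: at open 11/extend 1 a long gap is already score-prohibitive, which
bounds gaps in practice without extra DP state. The partial
(apicortin-type) p25alpha core is a *separate, shorter profile*, not a
low-coverage full-domain hit: the partial core behaves as its own conserved
unit, and modelling it separately keeps its hits' coverage and score
interpretable. When the full and partial profiles hit the same span, the
higher score wins and exact ties go to the full profile (a determinism
rule, not a biological claim).

**Threshold calibration.** The reporting threshold of each profile is the
99.9th percentile of its best local-alignment score against 1000 random
background sequences of length 500 (uniform residue composition), drawn
under a fixed internal seed (20230608). This pins the false-positive rate
on background sequence at about one hit per thousand sequences by
construction, replacing the E-value policy of database search tools with
something reproducible offline. Calibration length 500 matches the scale of
the proteins the scanner is pointed at; thresholds vary only weakly with
this choice because background local scores grow logarithmically with
sequence length.

## Motifs

The three diagnostic motifs are degenerate patterns (ordered residue sets):
`G-x-G-x-G-x-x-G-R`, `[LV]-x-x-x-[FY]-x-x-F`, `G-G-P`. Placement windows
are part of the definition: the anchor must begin within the first 15
residues of the domain span ("the very beginning" is not quantified
anywhere authoritative; 15 covers the offsets seen in the packaged seeds
and is a parameter), `GGP` must lie in the C-terminal half of the span and
the Rossmann block in the C-terminal third. Matching is exhaustive over
admissible offsets, so the scanner is trivially equivalent to brute-force
enumeration — a property the test suite asserts directly.

## The classifier

Classification is a total, deterministic function of the hits and motifs,
applied in a fixed order: (1) DCX + any p25alpha (full or partial) =
apicortin; (2) two or more p25alpha hits without DCX = multidomain; (3) a
single p25alpha hit is typed by the Rossmann motif (long) or else by the
**domain-span length** with cuts at 127 and 152 aa — midpoints of the
canonical ~120/~140/~160 lengths; (4) DCX alone or a long domain without
the Rossmann block stays `p25_unclassified`; (5) otherwise `none`.

Whole-protein length is deliberately *not* used: divergent short-type
proteins of ~121–124 aa would be miscalled truncated by any whole-length
rule, whereas their profile-defined domain span still lands in the short
band. Calls within ±7 aa of the truncated/short cut carry a "borderline"
note. The anchor and `GGP` motifs are recorded as evidence, never required:
the available descriptions present them as characteristic, not defining,
so treating them as hard requirements would silently drop divergent true
members. Fungal-type TPPPs are a known limitation: no discriminating
features are available to code against, so such sequences fall through the
other rules. A long N-terminal extension (>= 80 residues before the first
domain) is flagged but does not change the label.

## Alignment and identity

Pairwise alignment is global Needleman-Wunsch with affine gaps via the
three-state Gotoh recursion (BLOSUM62, open 10, extend 0.5; a length-$k$
gap costs $10 + 0.5(k-1)$), with a deterministic traceback (tie order
diagonal > up > left). The multiple aligner is classic progressive
alignment: identity distances $d = 1 - \mathrm{id}/100$ from all pairwise
alignments, a UPGMA guide tree, and profile–profile merges scored by the
mean pairwise substitution score of the two column populations (residue vs.
gap scores 0), with the same affine penalties. This is a deliberate,
documented divergence from the mBed/k-tuple heuristics of large-scale
aligners — at the family sizes this package targets (tens of sequences),
exact pairwise distances are affordable and simpler.

Percent identity is $100 \times$ identical columns / both-non-gap columns,
rounded half-up to two decimals. The denominator convention is isolated in
one function and switchable (`alignment_length`, `shorter_seq`) because
published identity tables rarely state theirs; when matching an external
table, compare conventions before concluding disagreement. Whether to trim
N-terminal extensions before computing identity is likewise exposed
(`trim` in the pipeline): trimming is conventionally described for tree
building, so full-length is the default for identity. Report binning
highlights <30, 30–40, 50–60 and >=60% bands, leaving 40–50 unhighlighted,
matching the conventional colouring of such tables.

## Trees

Bayesian inference is out of scope by design: re-implementing MCMC
phylogenetics would dwarf the rest of the package while adding nothing
testable at this scale. The substitute is Saitou–Nei neighbor joining on
identity distances, with three deliberate determinism rules: candidate
pairs minimising the Q criterion are broken lexicographically by
representative leaf label; negative branch lengths are clamped to zero with
the deficit moved to the sibling edge (preserving the joined pair's path
length); and the final three-node star uses the closed-form three-point
lengths. On additive matrices NJ provably recovers the generating tree,
and the suite checks this exactly on random trees of 4–10 taxa. A Poisson
correction $-\ln(1-d)$ is available but off by default — at the identity
ranges of interest (25–80%) the ranking of distances, which is what NJ
uses, is barely affected.

Support values come from column bootstrap: resample alignment columns with
replacement, rebuild the identity-distance NJ tree, and report for each
internal edge the fraction of replicates containing the same bipartition.
Supports are bit-reproducible given the seed. Clade statements are tested
with `is_monophyletic` after rooting on a stated outgroup; when no outgroup
is available the tree is midpoint-rooted, which is an interpretation and
flagged as such in the function's contract.

## The synthetic generator

The generator exists so that every pipeline stage can be validated without
downloads, against *known* truth. Templates are assembled from frozen
synthetic consensus cores (packaged under `inst/extdata/`, labelled
synthetic): a 160-aa master p25alpha core with the anchor at domain offset
2, `GGP` at 95 and the Rossmann block at 145; its 140-aa and 120-aa
prefixes for the short and truncated types; a 100-aa interior slice as the
apicortin-type partial core; and an unrelated 80-aa DCX core. Evolution
along a tree (user-supplied, or Yule rescaled to unit height) applies
per-site Poisson substitution — replacement residues uniform over the 20
amino acids, so a site hit at least once differs from the template with
probability $19/20$ — and Poisson indels with geometric lengths (mean 2).
Truth coordinates are carried through every indel via an origin map.

Defaults are 0.1 substitutions/site and 0.005 indels/site per unit branch
length with 8 taxa: on a unit-height tree this yields within-family
identities roughly in the 60–90% band and cross-architecture identities
well below, bracketing the divergence at which the classifier is expected
to operate; heavier regimes are exercised explicitly in tests. With
protection on (the default) the diagnostic motif sites are excluded from
substitution and indels, so the designed label remains well-defined at
arbitrary divergence; with `protect_motifs = FALSE` motifs decay and calls
drift toward `p25_unclassified`/truncated — emulating genuinely degenerate,
fast-evolving family members — which is also what the classifier *should*
do there. One documented stream-splitting rule governs reproducibility:
topology and template from `seed`, per-branch mutations from `seed + 1`.

What the generator does **not** emulate: empirical amino-acid
exchangeabilities (no BLOSUM/WAG-like rate matrix), site-rate
heterogeneity, compositional bias, and real disorder in N-terminal
extensions (flanks are uniform background). Passing the recovery tests
therefore shows the pipeline's logic is correct under its own model
assumptions — it does not certify performance on real, compositionally
biased proteomes, where profile seeds matter most.

## Numerical and degenerate-input choices

Internal coordinates are 0-based half-open; every written report is 1-based
inclusive. Ambiguous codons (containing `N`) translate to `X`; translation
is stop-to-stop with no start-codon requirement, since partial transcripts
truncate reading frames arbitrarily. Empty inputs, duplicate ids and
illegal characters fail fast with the offending record named. Inputs where
nothing passes scanning produce a distinct no-hit status (exit code 2 in
the CLI) with empty-but-valid reports. Equidistant matrices resolve by the
lexicographic tie rule and are asserted stable across runs. Profiles
round-trip through a documented JSON layout; trees through Newick with
supports as node labels (lengths preserved to 6 decimals).

## Problem sizes used in validation

The shipped validation uses sizes at which every oracle is exact or
statistically stable: exhaustive alignment enumeration up to length 6 over
a reduced alphabet; 1000 random sequences for motif-scanner equivalence and
for the background false-positive rate; 100 random additive matrices of
4–10 taxa for NJ; ten 20-taxon families (five architectures, two seeds) for
the mutated-regime classifier recovery plus five zero-rate families; and
five 8-taxon families with 100 bootstrap replicates on a fixed balanced
tree for support calibration. These are the package's chosen validation
conditions; all are recomputed from scratch by `scripts/acceptance.R`.
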