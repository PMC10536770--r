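---
title: "Methods: simulating and analysing FLC/MAF-like gene family evolution"
author: "genefam developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing FLC/MAF-like gene family evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `genefam`, the choices made
where the design was genuinely open, and what the synthetic data can and
cannot establish. It states no empirical result that the test-suite or
`scripts/acceptance.R` does not itself compute.

## 1. The scientific setting

Plant MADS-box genes of the FLC-like clade (FLC *s.str.* plus the
MAF-like genes, which split into MAF1/2/3 and MAF4/5) are unusual among
developmental regulators: they form tandem clusters that gain and lose
members rapidly, occasionally seed new loci by transposition, and are
multiplied wholesale by polyploidy. The three clades also experience
measurably different strengths of purifying selection. `genefam`
implements the full analysis cycle for such a family: simulation with
known truth, gene-tree estimation, reconciliation, mechanism
classification, and codon-model selection analysis.

## 2. The codon substitution model

The substitution process is the standard Goldman–Yang codon model over
the 61 sense codons of the universal genetic code. For codons $i \ne j$:

$$q_{ij} = \begin{cases}
0 & \text{more than one position differs} \\
\pi_j & \text{synonymous transversion} \\
\kappa \pi_j & \text{synonymous transition} \\
\omega \pi_j & \text{nonsynonymous transversion} \\
\omega \kappa \pi_j & \text{nonsynonymous transition}
\end{cases}$$

with the diagonal set so rows sum to zero and the matrix rescaled so that
the expected substitution rate at stationarity equals one; branch lengths
are therefore expected substitutions per codon. The matrix is reversible
by construction ($\pi_i q_{ij} = \pi_j q_{ji}$), so $P(t) = e^{Qt}$ is
computed by eigendecomposition of the symmetrised generator.

**Branch model.** Every gene-tree branch carries a class label
(`background`, `MAF45`, `MAF123`, `FLC_sstr`). Model M0 shares one
$\omega$ across all branches (np = #branches + 1 (κ) + 1 (ω) + 9 (F3x4));
Mb gives each class its own $\omega$ (np + 3). Stems between clades and
the outgroup are background — the crown clade of each class carries its
label, matching the convention that "branches leading to" a clade are
counted conservatively.

**Frequencies.** F3x4: empirical nucleotide frequencies per codon
position (pseudocount 0.5 per nucleotide per position against zeros),
multiplied, stops removed, renormalised. A uniform-frequency alternative
exists for controlled experiments. Frequencies are fixed during fitting,
as in standard practice.

**Likelihood.** Felsenstein pruning over codon site patterns (identical
columns collapsed), with per-node scalar rescaling against underflow.
Gaps and ambiguous codons are missing data (partial likelihood one).
Correctness is pinned by a brute-force oracle that enumerates all
internal-state assignments on trees with up to four leaves.

**Optimisation.** Coordinate cycles: (a) every branch length is optimised
by Brent's method using cached inside/outside partial likelihoods
(refreshed every few branches to bound staleness); (b) $\kappa$, the
$\omega$'s *and one branch-length scale factor per class* are refined
jointly by L-BFGS-B on the log scale. The scale factors matter: $\omega$
and the within-class branch lengths are ridge-coupled, and pure
coordinate cycling stalls on that ridge (observed as starts terminating
~0.3 lnL apart); letting the quasi-Newton step move along the ridge makes
all three standard starts ($\omega_0 \in \{0.5, 1, 2\}$) converge to the
same optimum. Cycles stop when the improvement drops below $10^{-6}$ lnL
(hard cap 200 cycles). Convergence is declared only when at least two of
the three starts agree within $10^{-3}$ lnL. Bounds: $\kappa \in [0.01,
20]$, $\omega \in [10^{-4}, 20]$, branch lengths $\in [0, 10]$. The fit
was cross-validated against an independent joint BFGS optimisation over
all parameters on a small problem (agreement ~$3\times10^{-6}$ lnL).

**LRT.** $2\Delta\mathrm{lnL}$ against $\chi^2$ with $\Delta np$ degrees
of freedom (3 for Mb vs M0). No boundary-mixture correction is needed:
none of the tested parameters sits on a boundary under the null.

## 3. The forward simulator

Each gene lineage evolves by independent Poisson processes with per-unit
branch-length rates for tandem duplication, tandem triplication (atomic:
one event, two extra adjacent copies, represented as two simultaneous
binary nodes in the true gene tree), inverted duplication, segmental
duplication, transposed duplication, and loss. Optional per-class rate
multipliers (`rate_scale_by_class`) reproduce the family's central
asymmetry — FLC s.str. turnover is far lower than MAF turnover — which no
single global rate set can produce.

Coordinates follow the generating mechanism: tandem/inverted copies land
2–50 kbp (uniform) downstream of the parent on the same scaffold
(inverted copies on the opposite strand); segmental copies land 500–2000
kbp away on the same scaffold; transposed copies get a fresh scaffold.
WGD/WGT branches duplicate *every* lineage cluster-wise onto parallel
sub-genome scaffolds (`_wgd2`, `_wgt2`, `_wgt3`), each gene retained with
the configured probability. Gene models are the canonical seven coding
exons (first exon MADS-box-sized) with 300 bp introns; the default 196
codons approximates a real FLC-like coding sequence.

Forced events make preset histories reproducible: the
`brassicaceae_like` preset starts from a **single** ancestral gene,
forces the FLC-vs-MAF tandem duplication onto the Brassicaceae stem
(after the Tarenaya-like outgroup diverged — this is what makes the
outgroup's genes monophyletic and usable for rooting, and puts two genes
in the ancestor of Brassicaceae), and forces the MAF1/2/3-vs-MAF4/5
duplication onto the core stem after the Aethionema-like species
branched off.

**Calibration (chosen once, not revisited).** Preset rates (tandem 0.7,
triplication 0.15, inverted 0.15, segmental 0.08, transposed 0.15, loss
0.6 per lineage per substitution unit; FLC s.str. scaled by 0.15,
background by 0.4) were calibrated to a single target: per-species
MAF-like copy numbers spanning roughly one to nine, with FLC s.str.
mostly one to three. Branch lengths of the stylised 30-tip species tree
total ~0.45 substitutions/codon root-to-tip. The simulation is *not* a
fit to any real event map.

**What a green test does not establish.** The generator draws root
sequences from the stationary distribution rather than from a real FLC
sequence; it has no introns/UTR content, no pseudogenes, no gene
conversion, no rate heterogeneity across sites, and coordinates never
collide with other (non-family) genes. Passing recovery tests therefore
demonstrates internal consistency of inference and simulation under the
stated model, not performance on real genomes.

## 4. Gene trees

The paper-scale pipeline aligns proteins with external tools; here the
simulator emits gap-free codon alignments, and real alignments are
accepted as input. Tree estimation deliberately substitutes a fast,
fully reproducible stack for an ML search: Kimura-corrected protein
distances $d = -\ln(1 - p - 0.2p^2)$ over pairwise gap-free columns
(saturation capped at 5 with a warning), Saitou–Nei neighbor joining with
deterministic lexicographic tie-breaking and negative-branch clamping
(deficit moved to the sibling), and bootstrap support by column
resampling. Rooting uses the outgroup when one exists (root at the
midpoint of the separating edge) and falls back to midpoint rooting.
Manual alignment trimming is replaced by an explicit two-threshold rule
(gap fraction ≤ 0.5, majority-residue frequency ≥ 0.1, configurable);
the thresholds are conventions, not fits — the original curation was
manual and irreproducible.

## 5. Reconciliation

LCA mapping; duplication iff a child maps to the same species node;
losses by the parsimony walk (one loss on the "other child" branch of
every species node the copy crossed without surviving descendants on
that side, plus one at a duplication's own node when its mapping differs
from the child's). Ancestral copy numbers count, per species node,
observed speciation/leaf gene nodes mapped there, inferred crossings,
and duplication-born copies; nothing is inferred above the family root's
mapping. Flow conservation (leaf counts = observed per-species counts)
is asserted internally on every run. Polytomies are rejected, never
auto-resolved — silent resolution would change the event counts that are
the analysis's headline output. A support-threshold collapse hook exists
(`collapse_weak_branches`) but is off by default.

## 6. Mechanism classification

Decision boundaries (defaults; all configurable): tandem/inverted ≤ 100
kbp boundary-to-boundary gap; segmental > 500 kbp; the 100–500 kbp zone
is segmental with a low-confidence flag; transposed requires the absence
of *any* same-scaffold witness pair, not merely a large distance (a
same-scaffold pair at any distance is positional evidence against
transposition). Distances are measured between nearest gene boundaries;
the alternative (MADS-box to MADS-box) changes distances by a few kbp
and no calls at the default thresholds.

Triplication collapsing merges a tandem-type duplication with a
tandem-type duplication at its **direct child** node on the **same**
species branch when the three copies (one from each resulting clade, one
species) are mutually within the tandem threshold on one scaffold — and
only when the connecting edge is (near-)simultaneous. An atomic
triplication produces two binary nodes
at the same instant, so the connecting edge has length zero; sequential
tandem events have positive separation. The default simultaneity
tolerance is $10^{-3}$ substitutions/codon — numerical slack above zero,
small enough that sequential events on ordinary branches do not merge.
Without this condition, piles of same-branch tandem events are
combinatorially ambiguous and classification accuracy degrades.

Cross-scaffold calls on annotated WGD/WGT branches are relabelled as
retention events; two or more cross-scaffold co-duplications on an
*unannotated* branch are flagged "possible unannotated WGD" (the
watercress-like signature: a whole cluster doubled onto another
scaffold).

## 7. Numerical and degenerate-input choices

* Internal coordinates 0-based half-open; on-disk 1-based inclusive.
* Terminal stop codons are stripped silently by translation; internal
  stops are fatal (pseudogene calling is out of scope).
* Transition probabilities clamp tiny negative eigen-round-off to zero;
  rows re-sum to one within $10^{-10}$.
* NJ Q-matrix ties break by the lexicographically smallest pair of
  cluster representatives; identical seeds give byte-identical outputs
  everywhere (single global RNG stream per entry point).
* A gene family that goes extinct in simulation is reported
  (`extinct = TRUE`), not an error.

## 8. Known limitations

* The branch-class labelling of an *inferred* tree is transferred from
  crown-clade tip sets; genes transposed between clades would be
  mislabelled (none are generated).
* The selection fit cost grows roughly linearly in branches × site
  patterns; families with hundreds of genes are better analysed on a
  pruned representative tree.
* The classifier cannot distinguish a true atomic triplication from two
  tandem duplications in immediate succession when branch lengths carry
  no signal (zero-length edges from identical sequences).
* Bootstrap support on very short alignments can saturate the distance
  correction; saturated pairs are capped, which compresses deep
  branches.
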