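---
title: "Coevolution networks of protein domains: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coevolution networks of protein domains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Residue positions that change together across a protein family mark
structural or functional coupling: a contact that must preserve packing or
charge complementarity, or an allosteric pathway whose elements co-adapt.
CoevoNet implements a network view of such couplings, developed around the
bacterial flagellar rotor switch proteins FliG and FliM: rather than only
asking *which pairs* of positions covary (contact prediction), it asks how
strongly *whole domains, inter-domain blocks, contact patches and
mutation-defined position sets* are wired together, and calibrates every
quantity against a shuffled-alignment null.

## The estimation chain

Starting from a multiple sequence alignment (rows = homologous sequences,
columns = residue positions, gaps treated as a 22nd symbol together with an
"unknown" class for non-standard residues):

1. **Pair frequencies** (`pairFrequencies`). Weighted joint symbol counts
   for every column pair. Redundancy is down-weighted by identity
   clustering: each sequence has weight $1/n_s$ where $n_s$ counts the
   sequences within fractional identity $\ge \theta$ of it
   ($\theta = 0.62$ by default). A uniform pseudocount of 1 per cell of each pair table (i.e. per
   symbol pair) regularizes the frequencies; this deliberately heavy,
   estimator-style smoothing also damps the finite-sample mutual
   information noise that otherwise accumulates between high-entropy
   column pairs and lets it dominate the network centrality.
2. **Mutual information** (`miMatrix`).
   $MI_{ij} = S_i + S_j - S_{ij}$ in bits, with the per-column Shannon
   entropy $S_i = -\sum_j p_{ij}\log_2 p_{ij}$ on the diagonal so the
   matrix behaves like a covariance. A joint-entropy normalization
   ($nMI = MI/S_{ij}$) is available but **off by default**: on alignments
   with a steep conservation gradient, dividing by a tiny $S_{ij}$ between
   conserved column pairs inflates the variance of noise couplings there,
   and the null-library centrality then *anti*-correlates with entropy —
   the opposite of the residual-correlation background the calibration
   assumes (conserved columns should carry *less* finite-sample
   correlation noise, not more). With plain MI the null centrality
   co-varies positively with entropy, as the method expects.
3. **Average-product correction** (`apcCorrect`),
   $M_{ij} - \bar M_i \bar M_j / \bar M$ over off-diagonal entries,
   removing the background column-wise coupling bias.
4. **Sparse inverse covariance** (`sparseInverse`). The corrected matrix
   is shrunk toward the identity by the smallest $\lambda$ that lifts its
   minimum eigenvalue to $10^{-3}$, then inverted under an L1 penalty
   ($\rho = 10^{-3}$ by default) with a graphical-lasso block coordinate
   descent (implemented in C++ in this package; at $\rho = 0$ the result
   is the exact inverse, which the tests verify against `solve()`).
5. **Direct information** (`directInformation`),
   $D_{ij} = W_{ij}/(W_{ii}W_{jj})$ from the precision matrix $W$. The
   inverse of a covariance-like matrix carries positively covarying pairs
   as *negative* off-diagonals (sign-flipped partial correlations), so
   the orchestrator `coevolutionMatrix()` negates the ratio
   (`flipSign = TRUE`) to orient the score with coevolved pairs positive —
   the orientation in which "positive correlations" measure coevolution
   and the upper-tail thresholds below make sense.
6. **Column-mean normalization** (`normalizeMatrix`),
   $D'_{ij} = D_{ij} - (\bar D_i + \bar D_j)/2$, centring the coupling
   distribution per position. One pass does not zero the column means
   exactly: the off-diagonal column means contract by the exact factor
   $L/(2(L-1))$ per pass, which is what the tests assert. The diagonal is
   masked throughout and never enters any mean, threshold or count.

## The null library

All significance and all normalization come from one construction
(`buildNullLibrary`): $K$ copies of the alignment whose columns are each
independently permuted (`shuffleColumns`). Shuffling preserves every
per-column symbol multiset — hence the entropy profile — while destroying
inter-column correlations, so matrices computed from shuffled alignments
measure the residual background created by finite depth, composition and
the estimator itself. From the library the package keeps pooled
off-diagonal moments (for the 3σ edge threshold), per-position centrality
means $E_R$ and deviations (for difference profiles and the 2σ node
rule), the member centrality profiles, and pooled full-matrix aggregates
(the "randomized" reference row). The default is $K = 100$; the test
suite and the synthetic reference analyses use $K = 10$–$20$, with the
correspondingly wider $3/\sqrt{K}$ tolerance on the self-normalization
identity. Member $m$ is seeded with $\mathrm{seed} + m$, so the library
is reproducible and members are independent.

## Network quantities

- **Centrality** (`eigenCentrality`): the principal eigenvector $E$ of
  the coupling matrix with negative entries clipped to zero (the
  unclipped matrix is kept for all sums and thresholds). Power iteration
  with a diagonal shift guards against bipartite-like spectra; $E$ is
  non-negative with unit L2 norm.
- **Node weights** (`nodeWeights`): sliding-window means of $E$ over
  $n = 6$ contiguous residues — about 1.5 helical turns, the scale of a
  structural element.
- **Difference profile** (`differenceProfile`):
  $\delta W_i = E_i - (M_E/M_R)\,E_{R,i}$, the real centrality minus the
  mean-ratio-scaled null centrality; zero-mean by construction.
- **Primary nodes** (`detectPrimaryNodes`): windows whose mean
  $\delta W$ exceeds the null window-weight mean by 2σ, with overlapping
  windows merged and each merged run reported at its peak-mode residue.
- **Strength and connectivity** (`networkMetrics`): for any selection of
  rows × columns, $S_M = (\Sigma_{>0}/N_{>0}) \big/
  (\Sigma^{rand}_{>0}/N^{rand}_{>0})$ and
  $C = (N_{corr}/N_{matrix}) \big/ (N^{rand}_{corr}/N^{rand}_{matrix})$,
  each normalized by the pooled randomized library. A symmetric
  selection counts both $(i,j)$ and $(j,i)$ and excludes the masked
  diagonal — the only convention consistent with
  $N_{matrix} = d_1 d_2$. Every selection uses its own $N_{matrix}$.
- **3-node networks** (`threeNodeNetwork`): all ordered pairs between
  the windows of the top three primary nodes
  ($N_{matrix} = 2\sum_{a<b}|a||b|$; intra-node pairs excluded). The
  published counts for such networks used node windows of unreported
  sizes, so only the aggregate-derived strengths — not the element
  counts — are comparable across implementations.
- **Mutation networks** (`buildMask`, `maskedNetwork`,
  `dummyPopulation`): a binary mask over all off-diagonal pairs of a
  mutated-position list (equivalently the symmetric sub-matrix on those
  positions), with significance from populations of random equal-size
  lists; dummy/real ratios below 1 mean the real list targets stronger
  features than chance. Dummies sample positions uniformly without
  replacement by default; a contiguous-block mode is available because
  the original construction's contiguity is not decidable from its
  description.

## Structure mapping

PDB structures (first model, highest-occupancy altloc, no waters or
hetero atoms) are mapped to alignment columns either through a named
reference row — with a hard residue-type check at every mapped position —
or by threading the structure sequence into the alignment via global
pairwise alignment (BLOSUM62), with a configurable identity floor (0.3)
below which mapping aborts. Downstream: Cα distance matrices; contact
statistics with classes contact $[0, 12)$ Å, intermediate $[12, 20]$ Å
and long-range $(20, \infty)$ Å (boundaries land on the non-contact side,
matching the strict inequalities of the published classification);
per-class coupling means and the fraction $F$ above the 3σ threshold;
solvent accessibility by Shrake–Rupley sphere sampling (probe 1.4 Å,
960 points per atom by default — doubling the sampling moves per-residue
areas by under 2%); conserved surface patches as maximal runs of more
than 4 columns where conservation and accessibility both strictly exceed
their profile means; and least-squares superposition RMSD via the Kabsch
SVD with reflection guard. Conservation for patches defaults to
$1 - S_i/\max(S)$, an entropy proxy chosen because evolutionary-rate
scores require a phylogeny; any external per-column score can be
supplied instead.

## The synthetic reference bundle

`generateMSA(syntheticSpec())` draws the study conditions the tests and
the synthetic analyses use: 300 sequences × 120 columns; a linear
per-column entropy gradient from 0.5 to 3.5 bits (each column is a
consensus-plus-uniform-background distribution whose consensus
probability is solved from the target entropy); a 5% per-column gap
rate, a realistic order of magnitude for curated domain alignments;
and 8 planted covarying pairs at coupling 0.9, laid out across two
6-residue segments (columns 30–35 ↔ 80–85, plus two crossed pairs
re-using columns), so the planted pairs double as planted network node
segments. Couplings are bijective symbol maps diluted by $c$: with
probability $c$ the symbol at $j$ is a fixed permutation image of the
symbol at $i$, giving $MI \to S_i$ as $c \to 1$, analytically tractable
for the sampling oracles. The two crossed pairs deliberately share
columns and dilute each other — recovering at least 6 of the 8 pairs
above the 3σ threshold is the expected outcome under these conditions.

The toy structure (`generateStructure`) is an ideal α-helical Cα trace
(rise 1.5 Å, 100° twist, radius 2.3 Å) split into two parallel helical
segments offset so the planted contact pairs sit below 12 Å while chain
ends lie beyond 20 Å; constraint violations are an error, never silently
accepted.

What the generator does **not** emulate: phylogenetic correlation between
sequences (rows are exchangeable), insertion/deletion blocks, alignment
errors, and composition bias. Passing the recovery tests therefore shows
the estimation chain works under clean planted signal at realistic depth
and conservation structure; it does not certify performance on real
families, where tree structure and alignment quality dominate the error
budget.

## Numerical and design choices

- Entropy in bits (log base 2); gap and unknown are ordinary symbols.
- Estimator defaults: identity-cluster weighting at θ = 0.62 (switchable
  to none), pseudocount 1 per pair table, shrinkage to eigenvalue floor
  $10^{-3}$, glasso ρ = $10^{-3}$. The headline metrics depend on rank
  structure and aggregate counts, not on these regularizers.
- Negative couplings are never discarded: they are clipped only inside
  the centrality computation and excluded from "positive" sums by
  definition of those sums.
- "Positive correlations" means strictly > 0 after column-mean
  normalization.
- Concatenation of per-domain alignments pairs rows by the organism
  token of the header; duplicated keys keep their first occurrence
  (reported) in one-to-one mode, or replicate the unique counterpart in
  many-to-one mode (one regulator sequence paired with each of several
  paralogues). The deduplication order is first-occurrence; the original
  procedure's order is not documented, and the choice only affects which
  duplicate survives, not the metric definitions.
- The 2σ primary-node rule centres on the *null* window-weight mean by
  default (`center = "real"` is available): the null distribution is the
  stated calibration reference for both thresholds.
- The 3σ edge threshold pools mean and σ over all off-diagonal null
  entries; a per-position variant is available when the library retains
  its member matrices.
- Problem sizes in the shipped analyses (L = 120, N = 300, K = 10–20,
  100–200 dummies, 40 seeds for the asymmetry property) were chosen so
  each property is measured at comfortable statistical resolution on a
  single workstation.

## Known limitations

- The graphical lasso is a dense block coordinate descent — fine for
  domain-scale alignments (hundreds of columns), not tuned for
  genome-scale concatenations.
- Stockholm parsing covers the plain sequence-line dialect (annotations
  skipped); FASTA is the primary interchange format.
- PDB only (no mmCIF); first model; author residue numbering is carried
  through, insertion codes are not resolved into the map.
- Phylogenetic null models are out of scope: the shuffled library
  corrects for composition and depth, not for shared ancestry; the
  identity-cluster weighting is the only phylogeny mitigation.
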