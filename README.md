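# CoevoNet

Coevolution-network analysis of protein domains in R, developed around
the bacterial flagellar rotor switch proteins FliG and FliM.

Residue positions that substitute in a correlated way across a protein
family mark structural or functional coupling. CoevoNet estimates a
direct-information coupling matrix from a multiple sequence alignment,
turns it into a residue network, and measures — always against a
column-shuffled null — how strongly domains, inter-domain blocks,
structural contacts and mutation-defined position sets are wired
together. It is aimed at structural bioinformaticians studying
multi-domain signalling assemblies, where the question is less "which
pairs touch?" than "which modules coevolve, and through which nodes?".

## The method in brief

From an alignment (gaps count as a symbol), the estimation chain is

* weighted pair frequencies (identity-cluster weighting, θ = 0.62) →
  mutual information `MI_ij = S_i + S_j − S_ij` with the column entropy
  `S_i = −Σ_j p_ij log2 p_ij` on the diagonal → average-product
  correction → diagonal shrinkage + graphical-lasso sparse inverse →
  direct information `D_ij = W_ij/(W_ii·W_jj)` (sign-oriented so that
  coevolved pairs score positive) → per-column mean normalization.

Calibration comes from a library of K column-shuffled alignments, which
preserve each column's symbol multiset (hence entropy) while destroying
all inter-column correlation. The library supplies:

* the **3σ edge threshold** for "high-scoring" couplings,
* the null centrality profile `E_R` behind the difference profile
  `δW_i = E_i − (M_E/M_R)·E_R,i` and the **2σ primary-node rule**
  (6-residue windows, merged, reported at their peak mode),
* the randomized reference row for network **strength**
  `S_M = (Σ_{>0}/N_{>0}) / (Σ_rand/N_rand)` and **connectivity**
  `C = (N_corr/N_matrix) / (N_corr_rand/N_matrix_rand)`.

Mutation-defined sub-networks (e.g. CW/CCW rotation-biasing lesions) are
binary masks over all pairs of mutated positions; their significance is
judged against populations of random equal-size position lists. With a
structure, high-scoring couplings are classified by Cα distance
(contact < 12 Å, long-range > 20 Å), and conserved solvent-accessible
surface patches are detected from entropy-based conservation plus
Shrake–Rupley accessibility.

## Worked example

The package ships a synthetic-data generator whose defaults define a
reference bundle: 300 sequences × 120 columns, an entropy gradient of
0.5–3.5 bits, 5% gaps, and 8 planted covarying pairs at coupling 0.9
concentrated on two 6-residue segments (columns 30–35 ↔ 80–85).

```r
library(CoevoNet)

bundle <- generateMSA(syntheticSpec(seed = 11))
aln  <- bundle$alignment
D    <- coevolutionMatrix(aln)              # the coupling matrix
null <- buildNullLibrary(aln, K = 10, seed = 42)

## high-scoring edges: planted pairs pass the 3 sigma threshold
hs <- highScoringThreshold(D, null)
pairs <- bundle$truth$pairs
sum(mapply(function(i, j) hs$mask[i, j], pairs$i, pairs$j))
#> [1] 6

## primary nodes recover the planted segments
prof  <- differenceProfile(eigenCentrality(D), null)
detectPrimaryNodes(prof, null)
#>    node start end peak           W
#> 16    1    16  21   17 0.005925580
#> 27    2    27  37   34 0.010751116
#> 64    3    64  69   64 0.006382596
#> 77    4    77  86   84 0.013372098

## strength and connectivity of the planted block, null-normalized
networkMetrics(D, rows = 30:35, cols = 80:85,
               nullRef = nullReference(null), label = "planted")
#> NetworkMetrics [planted]: sum_pos = 1.638, n_corr = 36, n_pos = 19, n_matrix = 36
#>   density = 1, strength = 0.08622, C = 1.008, S_M = 6.632
```

Six of the eight planted pairs clear the 3σ edge threshold (the two
crossed pairs share columns and dilute each other — the expected outcome
under these conditions). The two strongest detected nodes peak at
residues 34 and 84, inside the planted windows (the weaker extra nodes
are borderline 2σ excursions of the null-corrected profile). The planted
inter-segment block is ~6.6× stronger than the shuffled-library
reference at full connectivity.

An end-to-end run from a config (`runPipeline`) writes the coupling
matrix, profiles, node list, a metrics report with one row per network,
edge maps, patches and a provenance manifest; a thin command-line
wrapper with verbs `run`, `simulate`, `report` and `validate-config`
lives in `inst/scripts/coevnet.R`.

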