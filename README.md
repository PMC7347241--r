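# clonespect

Spectral clustering of B cell clonal families from AIRR-seq heavy-chain
data, combining junction similarity with shared somatic hypermutations.

## What it does

Members of a B cell clone descend from one V(D)J rearrangement and differ
only by somatic hypermutation (SHM), so clonal inference usually clusters
sequences with the same IGHV gene, IGHJ gene and junction length by the
Hamming distance between their junctions. `clonespect` implements that
recombination-based model and an *integrated* model that also uses
mutations shared by a sequence pair in the V and J segments — inherited
from common ancestors, these shared SHMs are a lineage fingerprint that
junction distance cannot see.

Within each VJ(l)-group the package computes, for every sequence pair
*i, j*, the junction/CDR3 Hamming distance `X_ij`, the normalised total and
shared mutation counts against the group's effective IUPAC germline,

    T_ij = (alpha + 2 beta + 2 gamma) / nu ,   H_ij = 2 gamma / nu ,

(alpha: mutated in one sequence; beta: both, different base; gamma: both,
same base), a 5-mer hot-spot damping `M_ij = prod_n (1 - mu(n))` over the
shared positions, and the SHM similarity

    S_ij = M_ij * exp(-(T_ij - H_ij)^2 / 2 sigma_T^2)
                * (1 - exp(-H_ij^2 / 2 sigma_H^2)) .

The weighted distance `W = X` (recombination model) or `W = (1 - S) X`
(integrated model) feeds a self-tuning spectral clustering: per-sequence
local scales from a density-gap search, Gaussian kernel
`K_ij = exp(-W_ij^2 / w_i w_j)`, Laplacian `L = D - K`, eigen-gap choice of
the number of clones, k-means on the leading eigenvectors. Four
configurations are available: `ham-junc`, `ham-cdr3`, `ham-shm-junc`,
`ham-shm-cdr3`.

The package also contains a ground-truth repertoire simulator (random
V(D)J recombination from a germline pool, gamma clone sizes, stochastic
branching lineage trees, 5-mer context-dependent substitutions) and the
evaluation protocols used to validate clonal inference: pairwise
sensitivity/specificity/precision, shared-mutation prevalence and
negative-control enrichment, and cross-individual spike-in specificity.

## Worked example

```r
library(clonespect)

sim <- simulate_repertoire(sim_params(), seed = 42)   # labelled repertoire
rs  <- collapse_identical(filter_productive(sim$rearrangements))
part <- assign_clones(rs, method = "integrated", target = "cdr3", seed = 1)
part

truth <- setNames(sim$truth$clone_id, sim$truth$sequence_id)
round(confusion_metrics(pairwise_confusion(truth[names(part$assignments)],
                                           part$assignments)), 4)

prev <- shared_shm_prevalence(sim$rearrangements, sim$truth)
```

which prints

```
clone partition (ham-shm-cdr3): 2284 sequence(s), 193 clone(s), 127 group(s)
sensitivity specificity   precision
     0.9971      1.0000      0.9963
```

The simulated repertoire holds 2,284 sequences in 173 true clones; the
integrated CDR3-targeted model recovers 99.7% of truly clonal sequence
pairs (sensitivity), keeps unrelated pairs apart essentially perfectly
(specificity 1.0000), and 99.6% of the pairs it links are real
(precision). In this run 92% of non-singleton clones contained at least
one pair sharing a V/J mutation — the signal the integrated model taps.

On real data, start from an AIRR or Change-O TSV instead:

```r
rs <- read_rearrangements("repertoire.tsv")           # or dialect = "changeo"
rs <- collapse_identical(filter_productive(rs))
part <- assign_clones(rs, method = "integrated", target = "cdr3", seed = 1)
write_clones(rs, part, "repertoire_clones.tsv")       # adds clone_id column
```

A thin command-line wrapper lives in `inst/cli/clonespect.R`
(`define-clones`, `simulate`, `evaluate`, `spike-specificity`).

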