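# ugtregio

Predicting the acceptor regioselectivity of flavonoid
UDP-glycosyltransferases (UGTs) — e.g. 3-O versus 7-O glucosylation —
from primary sequence and annotations of the seven acceptor-pocket loop
regions.

Flavonoid UGTs share a common fold and often diverge heavily in sequence
while sharing a regioselectivity class, so whole-sequence similarity is a
poor guide to function.  This package targets the loops lining the
acceptor pocket instead.  It is written for computational biologists
studying fine functional classification of closely related enzymes, and
for anyone who wants a worked, tested implementation of elastic
time-series distances over residue-descriptor series.

## Method in brief

* Each residue type is modeled as a rooted side-chain graph (atoms =
  nodes, bonds = length-weighted edges) from which seven indices are
  computed: reach, branching density, forking index, net partial charge,
  average polarity, and hydrogen-bond acceptor/donor indices.  The
  covarying indices are orthogonalized by correlation PCA; the PC scores
  are the working residue encoding.
* Each annotated loop of a protein becomes seven short numeric series
  (one per PC).  Two loops are compared with elastic distances — dynamic
  time warping (DTW), longest common subsequence (LCSS), or minimal
  variance matching (MVM) — and a protein-level distance is the sum over
  any chosen subset of loops `a`–`g` and index components:

  d(u, v) = Σ_{loop ∈ L} Σ_{index ∈ I} d_elastic(u[loop, index], v[loop, index])

* Classifiers: kNN on the distance sums; an RBF SVM on
  dissimilarity-space feature vectors (a record is represented by its
  distances to the training panel); and a hierarchical Bayesian neural
  network on fixed-length covering-window vectors, with per-group
  Gaussian priors whose precisions carry Gamma(α/2, α/(2w)) hyperpriors,
  trained by alternating Hamiltonian Monte Carlo and conjugate Gibbs
  updates.
* An exhaustive 3NN leave-one-out search over all
  (2⁷−1)·(2⁵−1) = 3937 loop × index combinations, with a mode analysis
  that flags loop subsets whose small loss pattern is stable across
  index choices — the signature of loop-confined class signal.
* A reciprocal-alignment-score distance (BLOSUM62, affine gaps) provides
  the classical baseline, and seeded synthetic generators with planted,
  loop-confined signal make the whole pipeline testable end to end.

## Worked example

Generate a UGT-like panel with class signal planted in loops `b` and
`e`, run the loop–index search, and ask which loop subsets qualify:

```r
library(ugtregio)

sim  <- simulate_ugt_data(sim_config(seed = 7))
sets <- encode_dataset(sim$records)
y    <- vapply(sim$records, `[[`, NA, "label")

res <- run_search(sets, y)          # 3937 combos, 3NN, leave-one-out
head(mode_analysis(res), 3)
#>   loop_key modal_pattern modal_size mode_frequency n_index_subsets qualifies
#> 1     abce             -          0             13              31      TRUE
#> 2    abcef             -          0             12              31      TRUE
#> 3     bcef             -          0             11              31      TRUE
```

Every qualifying loop subset contains a planted loop, and the modal loss
pattern is empty (`-`): restricted to the right loops, the classifier
makes no errors for 13 of the 31 index subsets.  The full distance sum
over all loops and indices does worse, because five loops contribute
only noise:

```r
D  <- distance_matrix(sets, distance_spec("DTW"))
lp <- knn_crossvalidate(D, y, cv_plan(names(y), "L1O"), k = 3)
format_loss_pattern(lp)
#> [1] "ugt13*, ugt19*"     # 2 errors; false positives starred
```

`rank_distance_functions(sets, y)` evaluates the DTW/LCSS/MVM ×
k ∈ {1,3,5} × {L1O, L6O} grid and orders metrics by crossvalidated
error; `loss_pattern_spectrum(res)` and `miss_frequency_by_record(res)`
summarize which records fail and how often.

The packaged metadata for the real 23-enzyme panel (ids, organisms,
accessions, regioselectivity classes) loads with `load_ugt_metadata()`;
sequences are deliberately not bundled (they are fetched by accession),
so the synthetic generators stand in wherever data are needed.

A command-line interface wrapping the same functions ships as
`inst/scripts/ugtregio` (subcommands `simulate`, `indices`, `encode`,
`dist`, `baseline`, `classify`, `search`, `bnn-train`).

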